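#' Published day-level summaries of the 2020 BLE card trial
#'
#' The raw observation logs of the 7-day New Zealand community trial of
#' Bluetooth proximity cards are not public, but its published summary
#' tables are: daily reciprocity (`r`, edge count `n_edges`, node count
#' `n_nodes`) for the card and case-investigation networks, and the three
#' card-versus-report confusion matrices by proximity-class threshold.
#' These ship with the package so that every network and model statistic
#' derivable from them can be recomputed.
#'
#' For the card network the node count is 736 — the cards surviving the
#' symmetric-role filter, before the boundary-day trim; this is the only
#' node set whose densities reproduce the published adjusted-reciprocity
#' values. For the case-investigation network it is the 65 interviewed
#' participants retained in the card cohort.
#'
#' @return `trial_daily_reciprocity()`: a tibble with columns `dataset`,
#'   `date`, `day`, `r`, `n_edges`, `n_nodes`. `trial_confusion_matrices()`:
#'   a list of [confusion_matrix()] objects named by class set.
#' @export
trial_daily_reciprocity <- function() {
  path <- system.file("extdata", "trial_daily_reciprocity.csv",
                      package = "cardtrace", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$date <- as.Date(raw$date)
  tibble::as_tibble(raw)
}

#' @rdname trial_daily_reciprocity
#' @export
trial_confusion_matrices <- function() {
  path <- system.file("extdata", "trial_confusion_matrices.csv",
                      package = "cardtrace", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  out <- lapply(seq_len(nrow(raw)), function(i) {
    confusion_matrix(tn = raw$tn[i], fn = raw$fn[i], fp = raw$fp[i],
                     tp = raw$tp[i],
                     class_set = as.integer(strsplit(raw$classes[i], ",")[[1]]))
  })
  stats::setNames(out, raw$classes)
}

#' Reconstruct reciprocated edge counts from rounded daily reciprocity
#'
#' Published tables report reciprocity to 4 decimals alongside the total
#' edge count `n`. Because the reciprocated count is the integer `r * n`,
#' it is recoverable exactly by rounding, and the reconstruction is
#' verified: `round(successes / n, 4)` must reproduce the printed `r` or
#' the function stops.
#'
#' @param summary A tibble like [trial_daily_reciprocity()] with columns
#'   `r` and `n_edges`.
#' @return The input with integer columns `successes` (reciprocated edges)
#'   and `trials` (total edges) appended.
#' @export
reconstruct_reciprocity_counts <- function(summary = trial_daily_reciprocity()) {
  successes <- as.integer(round(summary$r * summary$n_edges))
  back <- round(successes / summary$n_edges, 4)
  bad <- which(abs(back - summary$r) > 5e-5)
  if (length(bad) > 0) {
    stop("Reconstructed counts do not round back to the printed r for row(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::mutate(summary, successes = successes,
                trials = as.integer(.data$n_edges))
}

#' Regenerate the daily reciprocity table from reconstructed counts
#'
#' From reciprocated/total edge counts and the node set size, recomputes
#' `r`, its binomial standard error, the network density, the adjusted
#' reciprocity and its jackknife standard error for every day, entirely
#' through the package's dyad-census machinery (counts determine the census:
#' `mutual = successes / 2`, `asymmetric = trials - successes`).
#'
#' @param counts Output of [reconstruct_reciprocity_counts()].
#' @return A tibble with one row per dataset-day: `dataset`, `date`, `day`,
#'   `r`, `sigma_r`, `a_bar`, `rho_hat`, `sigma_rho`, `n_edges`.
#' @export
regenerate_reciprocity_table <- function(counts = reconstruct_reciprocity_counts()) {
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    census <- census_from_counts(counts$successes[i], counts$trials[i],
                                 counts$n_nodes[i])
    rr <- reciprocity_r(census)
    a_bar <- network_density(census)
    tibble::tibble(
      dataset = counts$dataset[i], date = counts$date[i], day = counts$day[i],
      r = rr$r, sigma_r = rr$sigma_r, a_bar = a_bar,
      rho_hat = rho_hat(rr$r, a_bar),
      sigma_rho = jackknife_sigma_rho(census),
      n_edges = rr$n_edges
    )
  })
  dplyr::bind_rows(rows)
}

census_from_counts <- function(successes, trials, n_nodes) {
  if (successes %% 2 != 0) {
    stop("Reciprocated edge count must be even (two edges per mutual dyad).",
         call. = FALSE)
  }
  mutual <- successes / 2
  asymmetric <- trials - successes
  structure(list(mutual = mutual, asymmetric = asymmetric,
                 null = n_nodes * (n_nodes - 1) / 2 - mutual - asymmetric,
                 n_edges = trials, n_nodes = n_nodes),
            class = "dyad_census")
}

#' Grouped-binomial observations for the reciprocity-trend models
#'
#' Shapes the reconstructed daily counts into the 12-row grouped dataset
#' (5 card days, 7 case-investigation days) on which the nested
#' reciprocity-trend models are fitted.
#'
#' @param counts Output of [reconstruct_reciprocity_counts()].
#' @return A tibble: `dataset`, `day`, `successes`, `trials`.
#' @export
reciprocity_model_observations <- function(counts = reconstruct_reciprocity_counts()) {
  dplyr::select(counts, "dataset", "day", "successes", "trials")
}
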