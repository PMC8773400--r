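#' Dyad census of a directed network
#'
#' Classifies every unordered pair of nodes as mutual (both directed edges
#' present), asymmetric (exactly one), or null (neither). Satisfies the
#' census identities `mutual + asymmetric + null = N(N-1)/2` and
#' `2 * mutual + asymmetric = |edges|`.
#'
#' @param edges Two-column data frame / tibble of directed edges (`from`,
#'   `to`). Duplicate edges are collapsed; self-loops are invalid.
#' @param nodes Character vector: the explicit node set (may exceed the IDs
#'   appearing in `edges`).
#' @return An object of class `dyad_census`: a named list with `mutual`,
#'   `asymmetric`, `null`, `n_edges`, `n_nodes`.
#' @examples
#' dyad_census(data.frame(from = c("A", "B", "A"), to = c("B", "A", "C")),
#'             nodes = c("A", "B", "C"))
#' @export
dyad_census <- function(edges, nodes) {
  nodes <- unique(as.character(nodes))
  n <- length(nodes)
  if (n < 2) stop("A dyad census needs at least 2 nodes.", call. = FALSE)
  edges <- unique(tibble::tibble(from = as.character(edges$from),
                                 to = as.character(edges$to)))
  if (any(edges$from == edges$to)) {
    stop("Self-loops are not valid contact edges.", call. = FALSE)
  }
  bad <- setdiff(unique(c(edges$from, edges$to)), nodes)
  if (length(bad) > 0) {
    stop("Edges reference nodes outside the node set: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  pair <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to), sep = "|")
  per_pair <- table(pair)
  mutual <- sum(per_pair == 2L)
  asymmetric <- sum(per_pair == 1L)
  structure(list(mutual = mutual, asymmetric = asymmetric,
                 null = n * (n - 1) / 2 - mutual - asymmetric,
                 n_edges = nrow(edges), n_nodes = n),
            class = "dyad_census")
}

#' @export
print.dyad_census <- function(x, ...) {
  cat(sprintf("<dyad_census> N=%d: %d mutual, %d asymmetric, %d null (%d edges)\n",
              x$n_nodes, x$mutual, x$asymmetric, x$null, x$n_edges))
  invisible(x)
}

#' Traditional reciprocity r with binomial standard error
#'
#' The proportion of directed contact edges whose reverse edge also exists:
#' `r = 2m / (2m + a)` for `m` mutual and `a` asymmetric dyads. The standard
#' error uses the binomial form `sqrt(r(1-r)/n)` with `n` the total number
#' of edges.
#'
#' @param census A [dyad_census()].
#' @return A named list: `r`, `sigma_r`, `n_edges`.
#' @export
reciprocity_r <- function(census) {
  stopifnot(inherits(census, "dyad_census"))
  n <- 2 * census$mutual + census$asymmetric
  if (n == 0) stop("Reciprocity is undefined on an empty network.", call. = FALSE)
  r <- 2 * census$mutual / n
  list(r = r, sigma_r = sqrt(r * (1 - r) / n), n_edges = n)
}

#' Directed network density
#'
#' `a_bar = |edges| / (N (N - 1))` over the explicit node set — isolated
#' nodes dilute the density, so the node set must be the full cohort, not
#' just the active IDs.
#'
#' @param n_edges Number of directed edges (or a [dyad_census()]).
#' @param n_nodes Number of nodes; ignored when `n_edges` is a census.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(n_edges, n_nodes = NULL) {
  if (inherits(n_edges, "dyad_census")) {
    n_nodes <- n_edges$n_nodes
    n_edges <- n_edges$n_edges
  }
  if (is.null(n_nodes) || n_nodes < 2) {
    stop("Density needs at least 2 nodes.", call. = FALSE)
  }
  n_edges / (n_nodes * (n_nodes - 1))
}

#' Garlaschelli-Loffredo density-adjusted reciprocity
#'
#' `rho = (r - a_bar) / (1 - a_bar)`: the correlation-style reciprocity
#' measure that is 0 when edges reciprocate at chance level given the
#' density, 1 under perfect reciprocity, and tends to `r` as density tends
#' to 0.
#'
#' @param r Traditional reciprocity.
#' @param a_bar Network density (must be < 1).
#' @return The adjusted reciprocity.
#' @export
rho_hat <- function(r, a_bar) {
  if (any(a_bar >= 1)) stop("rho is undefined at density 1.", call. = FALSE)
  (r - a_bar) / (1 - a_bar)
}

#' Jackknife standard error for the adjusted reciprocity
#'
#' Leave-one-dyad-out: for each unordered pair, zero both directed entries,
#' recompute rho, and accumulate squared deviations from the full-data rho;
#' the estimate is the square root of the sum. Null dyads leave the network
#' unchanged except for the (unaffected) node set, so they contribute 0 and
#' are skipped; deleting a mutual dyad removes two edges and one mutual
#' pair, an asymmetric dyad one edge and one asymmetric pair.
#'
#' @param census A [dyad_census()] (edge/node counts fully determine every
#'   leave-one-out value).
#' @return The jackknife standard error.
#' @export
jackknife_sigma_rho <- function(census) {
  stopifnot(inherits(census, "dyad_census"))
  if (census$mutual + census$asymmetric < 2) {
    stop("Jackknife needs at least 2 non-null dyads.", call. = FALSE)
  }
  n_nodes <- census$n_nodes
  full <- rho_from_counts(census$mutual, census$asymmetric, n_nodes)
  drop_mutual <- rho_from_counts(census$mutual - 1, census$asymmetric, n_nodes)
  drop_asym <- rho_from_counts(census$mutual, census$asymmetric - 1, n_nodes)
  sq <- 0
  if (census$mutual > 0) sq <- sq + census$mutual * (drop_mutual - full)^2
  if (census$asymmetric > 0) sq <- sq + census$asymmetric * (drop_asym - full)^2
  sqrt(sq)
}

rho_from_counts <- function(mutual, asymmetric, n_nodes) {
  n_edges <- 2 * mutual + asymmetric
  if (n_edges == 0) return(NA_real_)
  r <- 2 * mutual / n_edges
  rho_hat(r, n_edges / (n_nodes * (n_nodes - 1)))
}

#' Full reciprocity estimate for one network
#'
#' @param edges Directed edge tibble (`from`, `to`).
#' @param nodes Explicit node set.
#' @return A one-row tibble: `r`, `sigma_r`, `a_bar`, `rho_hat`,
#'   `sigma_rho`, `n_edges`, plus the census counts.
#' @export
reciprocity_estimate <- function(edges, nodes) {
  census <- dyad_census(edges, nodes)
  rr <- reciprocity_r(census)
  a_bar <- network_density(census)
  tibble::tibble(
    r = rr$r, sigma_r = rr$sigma_r, a_bar = a_bar,
    rho_hat = rho_hat(rr$r, a_bar),
    sigma_rho = if (census$mutual + census$asymmetric >= 2) {
      jackknife_sigma_rho(census)
    } else NA_real_,
    n_edges = rr$n_edges,
    mutual = census$mutual, asymmetric = census$asymmetric, null = census$null
  )
}

#' Daily reciprocity table
#'
#' Applies [reciprocity_estimate()] to each day of a day-indexed edge list,
#' against a fixed node set.
#'
#' @param edges Edge tibble with a `date` column plus `from`, `to`.
#' @param nodes Explicit node set used for every day's density.
#' @return A tibble with one row per day.
#' @export
reciprocity_by_day <- function(edges, nodes) {
  edges |>
    dplyr::group_by(date = .data$date) |>
    dplyr::group_modify(~ reciprocity_estimate(.x, nodes)) |>
    dplyr::ungroup()
}

#' Pooled reciprocity across days with Wald and Agresti-Coull intervals
#'
#' Pools reciprocated and total edge counts over days:
#' `r = sum(2 m_d) / sum(2 m_d + a_d)`. The Wald interval is
#' `r +/- z sqrt(r(1-r)/n)`; the Agresti-Coull interval adds `z^2/2`
#' successes and `z^2` trials before applying the Wald form, which behaves
#' better at the small daily counts typical of interview data.
#'
#' @param reciprocated Vector of daily reciprocated edge counts (`2 m_d`),
#'   or a list of [dyad_census()] objects.
#' @param total Vector of daily total edge counts; ignored when censuses are
#'   supplied.
#' @param conf_level Confidence level (default 0.95).
#' @return A named list: `r`, `n`, `wald_ci`, `agresti_coull_ci`.
#' @export
pooled_reciprocity <- function(reciprocated, total = NULL, conf_level = 0.95) {
  if (is.list(reciprocated) && inherits(reciprocated[[1]], "dyad_census")) {
    total <- vapply(reciprocated, function(cc) 2 * cc$mutual + cc$asymmetric, 0)
    reciprocated <- vapply(reciprocated, function(cc) 2 * cc$mutual, 0)
  }
  stopifnot(length(reciprocated) == length(total), all(reciprocated <= total))
  x <- sum(reciprocated)
  n <- sum(total)
  if (n == 0) stop("No edges to pool.", call. = FALSE)
  z <- qnorm(1 - (1 - conf_level) / 2)
  r <- x / n
  wald <- r + c(-1, 1) * z * sqrt(r * (1 - r) / n)
  n_ac <- n + z^2
  p_ac <- (x + z^2 / 2) / n_ac
  ac <- p_ac + c(-1, 1) * z * sqrt(p_ac * (1 - p_ac) / n_ac)
  list(r = r, n = n,
       wald_ci = pmin(pmax(wald, 0), 1),
       agresti_coull_ci = pmin(pmax(ac, 0), 1))
}
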