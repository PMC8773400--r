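#' Define the dyad-day universe for concordance analysis
#'
#' The denominator of every card-versus-report confusion matrix: all ordered
#' (reporter, other) pairs, for every reporter in the interviewed cohort,
#' every node in the card network, and every analysis day. Self-pairs are
#' included; with 65 reporters, 736 card nodes and 5 days this gives the
#' 239,200 pair-days that the trial's published confusion matrices sum to.
#'
#' @param reporters Interviewed cohort IDs.
#' @param others Card-network node IDs.
#' @param days Vector of analysis dates.
#' @return An object of class `dyad_day_universe`.
#' @export
dyad_day_universe <- function(reporters, others, days) {
  structure(list(reporters = sort(unique(reporters)),
                 others = sort(unique(others)),
                 days = sort(unique(as.Date(days)))),
            class = "dyad_day_universe")
}

#' @export
print.dyad_day_universe <- function(x, ...) {
  cat(sprintf("<dyad_day_universe> %d reporters x %d others x %d days = %d pair-days\n",
              length(x$reporters), length(x$others), length(x$days),
              universe_size(x)))
  invisible(x)
}

#' @rdname dyad_day_universe
#' @param universe A `dyad_day_universe`.
#' @export
universe_size <- function(universe) {
  length(universe$reporters) * length(universe$others) * length(universe$days)
}

card_positive_pairs <- function(card_daily, class_set) {
  cols <- paste0("min_class", class_set)
  active <- card_daily[rowSums(card_daily[, cols, drop = FALSE]) > 0, ]
  # a pair-day is card-positive if EITHER direction logged contact
  unique(c(paste(active$observer_id, active$observed_id, active$day, sep = "|"),
           paste(active$observed_id, active$observer_id, active$day, sep = "|")))
}

report_positive_pairs <- function(report_daily) {
  unique(paste(report_daily$reporter_id, report_daily$contact_id,
               report_daily$date, sep = "|"))
}

#' Cross-tabulate card-detected and reported contact events
#'
#' Over every (reporter, other, day) in the universe: card-positive when
#' either direction's daily record has non-zero minutes summed over
#' `class_set`; report-positive when the reporter reported that contact that
#' day. Cells follow the report-as-truth convention: `tp` card+report,
#' `fn` report only, `fp` card only, `tn` neither.
#'
#' @param card_daily Daily dyad records (wide, from [aggregate_daily()]).
#' @param report_daily Reports tibble (`reporter_id`, `contact_id`, `date`).
#' @param universe A [dyad_day_universe()].
#' @param class_set Proximity classes counted as contact: `0`, `0:1`, or
#'   `0:2`.
#' @return An object of class `confusion_matrix`: `tn`, `fn`, `fp`, `tp`,
#'   `class_set`.
#' @export
build_confusion_matrix <- function(card_daily, report_daily, universe,
                                   class_set = 0:2) {
  stopifnot(inherits(universe, "dyad_day_universe"))
  check_universe_covers(card_daily, report_daily, universe)
  card_keys <- card_positive_pairs(
    dplyr::filter(card_daily, .data$day %in% universe$days), class_set)
  report_keys <- report_positive_pairs(
    dplyr::filter(report_daily, .data$date %in% universe$days))

  grid_keys <- with(
    expand.grid(r = universe$reporters, o = universe$others,
                d = as.character(universe$days), stringsAsFactors = FALSE),
    paste(r, o, d, sep = "|"))
  card_pos <- grid_keys %in% card_keys
  report_pos <- grid_keys %in% report_keys
  structure(list(
    tn = sum(!card_pos & !report_pos), fn = sum(!card_pos & report_pos),
    fp = sum(card_pos & !report_pos), tp = sum(card_pos & report_pos),
    class_set = class_set
  ), class = "confusion_matrix")
}

check_universe_covers <- function(card_daily, report_daily, universe) {
  ids <- union(universe$reporters, universe$others)
  in_days <- card_daily$day %in% universe$days
  bad <- setdiff(unique(c(card_daily$observer_id[in_days],
                          report_daily$reporter_id[report_daily$date %in% universe$days])),
                 ids)
  if (length(bad) > 0) {
    stop("Universe is missing IDs present in the data: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a confusion matrix from known cells
#'
#' @param tn,fn,fp,tp Cell counts (report-as-truth convention).
#' @param class_set Proximity classes the card threshold used.
#' @return A `confusion_matrix`.
#' @export
confusion_matrix <- function(tn, fn, fp, tp, class_set = 0:2) {
  structure(list(tn = tn, fn = fn, fp = fp, tp = tp, class_set = class_set),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> classes {%s}\n",
              paste(x$class_set, collapse = ",")))
  m <- matrix(c(x$tn, x$fn, x$fp, x$tp), 2, 2, byrow = TRUE,
              dimnames = list(Card = c("No Contact", "Contact"),
                              Report = c("No Contact", "Contact")))
  print(m)
  invisible(x)
}

#' Detection and non-reporting rates from a confusion matrix
#'
#' `reported_detected_pct`: percentage of reported contact events that cards
#' detected, `100 * tp / (tp + fn)` (the true positive rate, as a
#' percentage). `detected_unreported_pct`: percentage of card-detected
#' contact events that went unreported, `100 * fp / (fp + tp)`. `tpr` and
#' `fpr` are returned as proportions.
#'
#' @param cm A `confusion_matrix`.
#' @return A named list: `reported_detected_pct`, `detected_unreported_pct`,
#'   `tpr`, `fpr`.
#' @export
detection_rates <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$tp + cm$fn == 0) stop("No reported contact events: rates undefined.",
                               call. = FALSE)
  if (cm$tn + cm$fp == 0) stop("No report-negative pair-days: fpr undefined.",
                               call. = FALSE)
  tpr <- cm$tp / (cm$tp + cm$fn)
  list(
    reported_detected_pct = 100 * tpr,
    detected_unreported_pct = if (cm$fp + cm$tp > 0) 100 * cm$fp / (cm$fp + cm$tp) else 0,
    tpr = tpr,
    fpr = cm$fp / (cm$fp + cm$tn)
  )
}

#' Per-day true and false positive rates per proximity-class threshold
#'
#' Enlarging the class set can only add card-positive pair-days, so both
#' rates are non-decreasing in the threshold on any given day (a partial
#' ROC over the three card contact definitions).
#'
#' @inheritParams build_confusion_matrix
#' @param class_sets List of class sets to evaluate.
#' @return A tibble: `day`, `classes`, `tp`, `fn`, `fp`, `tn`, `tpr`,
#'   `fpr`; `tpr` is `NA` (flagged) on days with no reported events.
#' @export
daily_tpr_fpr <- function(card_daily, report_daily, universe,
                          class_sets = list(0, 0:1, 0:2)) {
  stopifnot(inherits(universe, "dyad_day_universe"))
  rows <- list()
  for (d in as.list(universe$days)) {
    day_universe <- dyad_day_universe(universe$reporters, universe$others, d)
    for (cs in class_sets) {
      cm <- build_confusion_matrix(card_daily, report_daily, day_universe, cs)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        day = d, classes = paste(cs, collapse = ","),
        tp = cm$tp, fn = cm$fn, fp = cm$fp, tn = cm$tn,
        tpr = if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else NA_real_,
        fpr = cm$fp / (cm$fp + cm$tn)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Non-compliance signatures in the card data
#'
#' Two signatures of cards not being worn: per day, the fraction of
#' reporters (participants with at least one reported event) whose cards
#' logged no interactions at all that day; and card dyad-days with class-0
#' durations at or above a threshold (default 22 hours) that no interview
#' report corroborates — the signature of household members leaving their
#' cards together at home.
#'
#' @param card_daily Daily dyad records.
#' @param report_daily Reports tibble.
#' @param interviewed IDs of the interviewed cohort.
#' @param days Analysis days.
#' @param threshold_hours Class-0 duration flag threshold in hours. A zero
#'   threshold flags every unreported class-0 contact (the minimum stored
#'   duration is one 2-minute record).
#' @return A list: `zero_interaction` (tibble `day`,
#'   `pct_zero_interaction_reporters`), `long_duration_flags` (tibble of
#'   flagged unreported dyad-days).
#' @export
noncompliance_summary <- function(card_daily, report_daily, interviewed, days,
                                  threshold_hours = 22) {
  days <- sort(unique(as.Date(days)))
  reporters <- intersect(interviewed, unique(report_daily$reporter_id))
  zero <- dplyr::bind_rows(lapply(as.list(days), function(d) {
    active <- unique(c(card_daily$observer_id[card_daily$day == d],
                       card_daily$observed_id[card_daily$day == d]))
    tibble::tibble(
      day = d,
      pct_zero_interaction_reporters =
        if (length(reporters) > 0) 100 * mean(!reporters %in% active) else NA_real_
    )
  }))

  report_keys <- report_positive_pairs(report_daily)
  flags <- card_daily |>
    dplyr::filter(.data$day %in% days,
                  .data$min_class0 >= max(threshold_hours * 60, 2)) |>
    dplyr::filter(!paste(.data$observer_id, .data$observed_id, .data$day, sep = "|")
                  %in% report_keys,
                  !paste(.data$observed_id, .data$observer_id, .data$day, sep = "|")
                  %in% report_keys)
  list(zero_interaction = zero, long_duration_flags = flags)
}
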