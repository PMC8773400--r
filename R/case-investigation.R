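#' Normalise raw interview reports
#'
#' Enforces the report invariants: no self-reports (error), durations of at
#' least 2 minutes (error), and at most one record per (reporter, contact,
#' date) — duplicates collapse to the longest duration with a warning,
#' since interview protocols record at most one contact event per person
#' per day.
#'
#' @param reports Tibble with columns `reporter_id`, `contact_id`, `date`
#'   (Date), `duration_min`.
#' @return The normalised reports tibble.
#' @export
normalise_reports <- function(reports) {
  if (any(reports$reporter_id == reports$contact_id)) {
    stop("Self-reported contact events are not valid.", call. = FALSE)
  }
  if (any(reports$duration_min < 2)) {
    stop("Reported durations must be at least 2 minutes.", call. = FALSE)
  }
  n0 <- nrow(reports)
  out <- reports |>
    dplyr::group_by(.data$reporter_id, .data$contact_id, .data$date) |>
    dplyr::summarise(duration_min = max(.data$duration_min), .groups = "drop")
  if (nrow(out) < n0) {
    warning(sprintf("Collapsed %d duplicate same-day report(s).", n0 - nrow(out)),
            call. = FALSE)
  }
  out
}

#' Build day-level directed report networks
#'
#' Each report becomes a directed edge reporter -> contact on its reported
#' date. The node set is supplied explicitly because density calculations
#' must include participants with no edges.
#'
#' @param reports Normalised reports tibble.
#' @param nodes Character vector: the network's node set.
#' @return Tibble of directed edges: `date`, `from`, `to`, `duration_min`.
#' @export
build_reported_dyads <- function(reports, nodes) {
  reports <- normalise_reports(reports)
  bad <- setdiff(unique(c(reports$reporter_id, reports$contact_id)), nodes)
  if (length(bad) > 0) {
    stop("Reports reference IDs outside the node set: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  edges <- reports |>
    dplyr::transmute(date = .data$date, from = .data$reporter_id,
                     to = .data$contact_id, duration_min = .data$duration_min) |>
    dplyr::arrange(.data$date, .data$from, .data$to)
  attr(edges, "nodes") <- sort(unique(nodes))
  edges
}

#' Restrict interview reports to the card cohort
#'
#' Keeps only reporters who are themselves in the card node set (cards with
#' both observing and observed activity) and who name at least one
#' card-cohort member among their contacts; contacts outside the cohort are
#' dropped from dyad analysis. This nests the interviewed subpopulation
#' within the card subpopulation so that the same people underlie the
#' reciprocity and concordance analyses.
#'
#' @param reports Normalised reports tibble.
#' @param card_node_ids Cards surviving the symmetric-role filter.
#' @param interviewed_ids All interviewed participant IDs.
#' @return A list: `reports` (kept reports, cohort contacts only),
#'   `retained_reporters`, and `exclusions` — a tibble
#'   (`reporter_id`, `category`) with categories `"no cohort contacts"`
#'   (every named contact outside the cohort) and `"not in card cohort"`
#'   (the reporter's own card failed the role filter or was never returned).
#' @export
restrict_to_card_cohort <- function(reports, card_node_ids, interviewed_ids) {
  reporters <- intersect(interviewed_ids, unique(reports$reporter_id))
  per_reporter <- reports |>
    dplyr::filter(.data$reporter_id %in% reporters) |>
    dplyr::group_by(.data$reporter_id) |>
    dplyr::summarise(any_cohort = any(.data$contact_id %in% card_node_ids),
                     .groups = "drop")
  no_cohort <- per_reporter$reporter_id[!per_reporter$any_cohort]
  remaining <- setdiff(per_reporter$reporter_id, no_cohort)
  not_in_cohort <- setdiff(remaining, card_node_ids)
  kept <- intersect(remaining, card_node_ids)

  exclusions <- dplyr::bind_rows(
    tibble::tibble(reporter_id = no_cohort, category = "no cohort contacts"),
    tibble::tibble(reporter_id = not_in_cohort, category = "not in card cohort")
  )
  out <- reports |>
    dplyr::filter(.data$reporter_id %in% kept,
                  .data$contact_id %in% card_node_ids)
  list(reports = out, retained_reporters = sort(kept), exclusions = exclusions)
}

#' Reassign unreciprocated reports to an adjacent day
#'
#' Date-misreporting sensitivity step: an unreciprocated directed edge
#' i -> j on day d moves to day d-1 or d+1 only if (a) i reported no contact
#' with j on that adjacent day and (b) j reported contact with i there, so
#' the move creates a mutual dyad. All conditions are evaluated against the
#' original network and every move is applied simultaneously (one-shot, no
#' cascading). When both adjacent days qualify, the earlier day wins.
#'
#' @param edges Day-indexed directed edge tibble (`date`, `from`, `to`).
#' @param dates Contiguous vector of valid trial dates.
#' @param prefer `"earlier"` (default) or `"later"`: tie-break when both
#'   adjacent days qualify.
#' @return A list: `edges` (adjusted tibble) and `moves`
#'   (`from`, `to`, `date`, `new_date`).
#' @export
reassign_unreciprocated_dates <- function(edges, dates, prefer = c("earlier", "later")) {
  prefer <- match.arg(prefer)
  dates <- sort(as.Date(dates))
  key <- function(d, f, t) paste(d, f, t, sep = "|")
  original <- key(edges$date, edges$from, edges$to)

  has_edge <- function(d, f, t) key(d, f, t) %in% original
  reciprocated <- has_edge(edges$date, edges$to, edges$from)

  candidate_ok <- function(d) {
    d %in% dates &
      !has_edge(d, edges$from, edges$to) &   # (a) no own report there
      has_edge(d, edges$to, edges$from)      # (b) partner reported there
  }
  prev_ok <- !reciprocated & candidate_ok(edges$date - 1)
  next_ok <- !reciprocated & candidate_ok(edges$date + 1)

  new_date <- edges$date
  if (prefer == "earlier") {
    new_date[next_ok] <- edges$date[next_ok] + 1
    new_date[prev_ok] <- edges$date[prev_ok] - 1
  } else {
    new_date[prev_ok] <- edges$date[prev_ok] - 1
    new_date[next_ok] <- edges$date[next_ok] + 1
  }

  moved <- new_date != edges$date
  moves <- tibble::tibble(from = edges$from[moved], to = edges$to[moved],
                          date = edges$date[moved], new_date = new_date[moved])
  out <- edges
  out$date <- new_date
  out <- dplyr::arrange(out, .data$date, .data$from, .data$to)
  attr(out, "nodes") <- attr(edges, "nodes")
  list(edges = out, moves = moves)
}

#' Read interview reports from CSV
#'
#' Expects the schema `reporter_id,contact_id,date_iso8601,duration_min`.
#'
#' @param path File path.
#' @return Reports tibble (`reporter_id`, `contact_id`, `date`,
#'   `duration_min`).
#' @export
read_reports_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  date_col <- if ("date_iso8601" %in% names(raw)) "date_iso8601" else "date"
  tibble::tibble(
    reporter_id = as.character(raw$reporter_id),
    contact_id = as.character(raw$contact_id),
    date = as.Date(raw[[date_col]]),
    duration_min = as.numeric(raw$duration_min)
  )
}
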