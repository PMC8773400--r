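#' Classify an RSSI value into a proximity class
#'
#' Discretises integer RSSI (dBm) into the card firmware's proximity classes:
#' class 0 for `[-50, -20]` (roughly 0-1 m), class 1 for `[-56, -50)`
#' (1-2 m), class 2 for `[-62, -56)` (2-4 m). Readings below -62 dBm fall
#' outside the storage range and map to `NA`; readings above -20 dBm exceed
#' the hardware ceiling and are clamped into class 0.
#'
#' @param rssi Integer vector of RSSI values in dBm.
#' @return Integer vector of classes 0, 1, 2, or `NA` for sub-floor readings.
#' @examples
#' classify_proximity(c(-45, -50, -56, -62, -63))
#' @export
classify_proximity <- function(rssi) {
  cls <- rep(NA_integer_, length(rssi))
  cls[rssi >= -62] <- 2L
  cls[rssi >= -56] <- 1L
  cls[rssi >= -50] <- 0L   # includes the > -20 dBm hardware-ceiling clamp
  cls
}

#' Build stored 2-minute records from raw 15-second readings
#'
#' Cards scan every 15 s and store a 2-minute record only when signal was
#' obtained continuously for the whole window: all 8 scheduled 15-second
#' slots must contain a reading at or above the -62 dBm floor. The stored
#' record's proximity class is determined by the maximum RSSI over the
#' window. Windows align to a 2-minute grid from the top of the hour.
#'
#' Duplicate readings within one 15-second slot keep the maximum RSSI, with
#' a warning.
#'
#' @param readings Tibble with columns `observer_id`, `observed_id`,
#'   `timestamp` (POSIXct), `rssi_dbm`.
#' @return Tibble of records: `observer_id`, `observed_id`, `window_start`
#'   (POSIXct), `proximity_class`.
#' @export
build_two_minute_records <- function(readings) {
  empty <- tibble::tibble(observer_id = character(), observed_id = character(),
                          window_start = as.POSIXct(character(), tz = "UTC"),
                          proximity_class = integer())
  if (nrow(readings) == 0) return(empty)
  tz <- attr(readings$timestamp, "tzone")
  if (is.null(tz) || !nzchar(tz)) tz <- "UTC"

  slotted <- readings |>
    dplyr::mutate(slot = floor(as.numeric(.data$timestamp) / 15)) |>
    dplyr::group_by(.data$observer_id, .data$observed_id, .data$slot)
  n_dup <- dplyr::n_groups(slotted)
  slotted <- dplyr::summarise(slotted, rssi_dbm = max(.data$rssi_dbm), .groups = "drop")
  if (nrow(slotted) < nrow(readings)) {
    warning(sprintf("%d duplicate reading(s) within a 15-s slot; kept the maximum RSSI.",
                    nrow(readings) - n_dup), call. = FALSE)
  }

  slotted |>
    dplyr::mutate(window = .data$slot %/% 8L) |>
    dplyr::group_by(.data$observer_id, .data$observed_id, .data$window) |>
    dplyr::summarise(n_slots = dplyr::n(),
                     min_rssi = min(.data$rssi_dbm),
                     max_rssi = max(.data$rssi_dbm), .groups = "drop") |>
    dplyr::filter(.data$n_slots == 8L, .data$min_rssi >= -62) |>
    dplyr::transmute(observer_id = .data$observer_id,
                     observed_id = .data$observed_id,
                     window_start = as.POSIXct(.data$window * 120,
                                               origin = "1970-01-01", tz = tz),
                     proximity_class = classify_proximity(.data$max_rssi))
}

#' Aggregate 2-minute records into 2-hour blocks
#'
#' Mirrors the card's long-term flash storage: per directed dyad and
#' even-hour 2-hour block, the number of stored 2-minute records at each
#' proximity class.
#'
#' @param records Output of [build_two_minute_records()].
#' @return Tibble: `observer_id`, `observed_id`, `block_start` (POSIXct),
#'   `proximity_class`, `n_two_min`.
#' @export
aggregate_two_hour <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(observer_id = character(), observed_id = character(),
                          block_start = as.POSIXct(character(), tz = "UTC"),
                          proximity_class = integer(), n_two_min = integer()))
  }
  records |>
    dplyr::mutate(block_start = lubridate::floor_date(.data$window_start, "2 hours")) |>
    dplyr::count(.data$observer_id, .data$observed_id, .data$block_start,
                 .data$proximity_class, name = "n_two_min")
}

#' Aggregate 2-hour blocks into daily dyad records
#'
#' Produces the day-level analysis table: per directed dyad and calendar
#' day, minutes of contact at each proximity class (2 minutes per stored
#' record), in wide form.
#'
#' @param blocks Output of [aggregate_two_hour()].
#' @return Tibble: `observer_id`, `observed_id`, `day` (Date), `min_class0`,
#'   `min_class1`, `min_class2`.
#' @export
aggregate_daily <- function(blocks) {
  empty <- tibble::tibble(observer_id = character(), observed_id = character(),
                          day = as.Date(character()), min_class0 = numeric(),
                          min_class1 = numeric(), min_class2 = numeric())
  if (nrow(blocks) == 0) return(empty)
  tz <- attr(blocks$block_start, "tzone")
  if (is.null(tz) || !nzchar(tz)) tz <- "UTC"
  blocks |>
    dplyr::mutate(day = as.Date(.data$block_start, tz = tz)) |>
    dplyr::group_by(.data$observer_id, .data$observed_id, .data$day,
                    .data$proximity_class) |>
    dplyr::summarise(minutes = 2 * sum(.data$n_two_min), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "proximity_class", values_from = "minutes",
                       names_prefix = "min_class", values_fill = 0) |>
    add_missing_class_cols() |>
    dplyr::select("observer_id", "observed_id", "day",
                  "min_class0", "min_class1", "min_class2") |>
    dplyr::arrange(.data$observer_id, .data$observed_id, .data$day)
}

add_missing_class_cols <- function(daily) {
  for (col in c("min_class0", "min_class1", "min_class2")) {
    if (!col %in% names(daily)) daily[[col]] <- 0
  }
  daily
}

#' Remove cards that never played both observing and observed roles
#'
#' A card can only corroborate an interaction if it both sees and is seen.
#' Cards appearing only as observers, or only as observed, are removed along
#' with all their records. Applied in a single pass (removal can leave other
#' cards one-sided; those are deliberately kept, matching a one-shot filter).
#'
#' @param daily Daily dyad tibble from [aggregate_daily()].
#' @return A list: `daily` (filtered records), `removed_ids` (character).
#' @export
filter_reciprocal_roles <- function(daily) {
  observers <- unique(daily$observer_id)
  observed <- unique(daily$observed_id)
  keep <- intersect(observers, observed)
  removed <- setdiff(union(observers, observed), keep)
  out <- daily |>
    dplyr::filter(.data$observer_id %in% keep, .data$observed_id %in% keep)
  list(daily = out, removed_ids = sort(removed))
}

#' Trim the anomalous first and last trial days
#'
#' Roll-out and collection on the boundary days inflate contact counts, so
#' records on `first_day` and `last_day` are dropped. Cards left with no
#' records at all are reported as removed.
#'
#' @param daily Daily dyad tibble.
#' @param first_day,last_day Dates to drop.
#' @return A list: `daily` (trimmed records), `removed_ids` (cards with no
#'   remaining records).
#' @export
trim_trial_days <- function(daily, first_day, last_day) {
  first_day <- as.Date(first_day)
  last_day <- as.Date(last_day)
  before <- union(unique(daily$observer_id), unique(daily$observed_id))
  out <- dplyr::filter(daily, .data$day != first_day, .data$day != last_day)
  if (nrow(daily) > 0 && nrow(out) == 0) {
    stop("Trimming the boundary days removed every record.", call. = FALSE)
  }
  after <- union(unique(out$observer_id), unique(out$observed_id))
  list(daily = out, removed_ids = sort(setdiff(before, after)))
}

#' Run the full card-data pipeline
#'
#' Raw readings to analysis-ready daily dyad records: 2-minute windowing,
#' 2-hour and daily aggregation, the symmetric-role filter, then the
#' boundary-day trim. The symmetric-role filter runs before the day trim,
#' and each removal is reported separately.
#'
#' @param readings Raw readings tibble.
#' @param first_day,last_day Boundary days to trim; `NULL` skips trimming.
#' @return A list: `daily` (final records), `daily_untrimmed` (after the
#'   role filter, before the trim), `removed_role_filter`,
#'   `removed_day_trim` (character ID vectors), `node_ids` (cards surviving
#'   the role filter — the node set used for network density).
#' @export
card_pipeline <- function(readings, first_day = NULL, last_day = NULL) {
  daily <- aggregate_daily(aggregate_two_hour(build_two_minute_records(readings)))
  role <- filter_reciprocal_roles(daily)
  node_ids <- sort(intersect(unique(role$daily$observer_id),
                             unique(role$daily$observed_id)))
  if (is.null(first_day) || is.null(last_day)) {
    return(list(daily = role$daily, daily_untrimmed = role$daily,
                removed_role_filter = role$removed_ids,
                removed_day_trim = character(0), node_ids = node_ids))
  }
  trim <- trim_trial_days(role$daily, first_day, last_day)
  list(daily = trim$daily, daily_untrimmed = role$daily,
       removed_role_filter = role$removed_ids,
       removed_day_trim = trim$removed_ids, node_ids = node_ids)
}

#' Read raw readings / write daily dyad records as CSV
#'
#' @param path File path. Readings CSV uses the schema
#'   `observer_id,observed_id,timestamp_iso8601,rssi_dbm`.
#' @return A readings tibble, or (for the writer) `path` invisibly.
#' @export
read_readings_csv <- function(path) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  tibble::tibble(
    observer_id = as.character(raw$observer_id),
    observed_id = as.character(raw$observed_id),
    timestamp = as.POSIXct(raw$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%S",
                           tz = "UTC"),
    rssi_dbm = as.integer(raw$rssi_dbm)
  )
}

#' @rdname read_readings_csv
#' @param daily Daily dyad tibble.
#' @export
write_daily_csv <- function(daily, path) {
  out <- as.data.frame(daily)
  out$day <- format(out$day, "%Y-%m-%d")
  names(out)[names(out) == "day"] <- "date"
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
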