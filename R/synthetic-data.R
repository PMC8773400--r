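#' Generate a synthetic trial population with household structure
#'
#' Assigns every participant to exactly one household, with household sizes
#' drawn from the configured size distribution. The last household is
#' truncated so the population size is met exactly.
#'
#' @param config A [generator_config()].
#' @return A tibble with columns `participant_id`, `household_id`.
#' @examples
#' generate_population(generator_config(n_participants = 10, seed = 3))
#' @export
generate_population <- function(config) {
  validate_generator_config(config)
  local_generator_seed(config, 1L)
  n <- config$n_participants
  sizes <- integer(0)
  while (sum(sizes) < n) {
    k <- max(64L, ceiling((n - sum(sizes)) / 2))
    sizes <- c(sizes, sample(seq_along(config$household_size_distribution), k,
                             replace = TRUE, prob = config$household_size_distribution))
  }
  sizes <- sizes[cumsum(sizes) - sizes < n]          # households that start before n
  sizes[length(sizes)] <- n - sum(sizes[-length(sizes)])
  tibble::tibble(
    participant_id = sprintf("P%04d", seq_len(n)),
    household_id = sprintf("H%04d", rep(seq_along(sizes), sizes))
  )
}

#' Generate ground-truth dyadic contact events
#'
#' Draws community contact events as a Poisson process over random pairs
#' (expected `contact_rate` events per participant per day) plus additional
#' within-household events for each cohabiting pair. Each event carries a
#' true distance in (0, 4] m and a duration of at least 2 minutes. Events are
#' stored with the unordered pair in canonical order (`person_a < person_b`).
#'
#' @param population Output of [generate_population()].
#' @param config A [generator_config()].
#' @return A tibble with columns `person_a`, `person_b`, `day`, `start_time`,
#'   `duration_min`, `distance_m`.
#' @export
generate_true_contacts <- function(population, config) {
  validate_generator_config(config)
  if (nrow(population) == 0) stop("`population` is empty.", call. = FALSE)
  local_generator_seed(config, 2L)
  ids <- population$participant_id
  n <- length(ids)

  events <- list()
  hh_pairs <- household_pairs(population)
  for (day in seq_len(config$n_days)) {
    # community events: each event involves two participants, so n*rate/2 events
    n_ev <- if (config$contact_rate > 0 && n >= 2) {
      rpois(1L, config$contact_rate * n / 2)
    } else 0L
    if (n_ev > 0) {
      a <- sample(n, n_ev, replace = TRUE)
      b_raw <- sample(n - 1L, n_ev, replace = TRUE)
      b <- ifelse(b_raw >= a, b_raw + 1L, b_raw)    # uniform over partners != a
      events[[length(events) + 1L]] <- tibble::tibble(
        person_a = ids[pmin(a, b)], person_b = ids[pmax(a, b)], day = day,
        distance_m = draw_distances(n_ev, config)
      )
    }
    if (nrow(hh_pairs) > 0 && config$household_contact_rate > 0) {
      counts <- rpois(nrow(hh_pairs), config$household_contact_rate)
      keep <- rep(seq_len(nrow(hh_pairs)), counts)
      if (length(keep) > 0) {
        events[[length(events) + 1L]] <- tibble::tibble(
          person_a = hh_pairs$person_a[keep], person_b = hh_pairs$person_b[keep],
          day = day,
          distance_m = runif(length(keep), 0.2, 1)  # household contacts are close
        )
      }
    }
  }
  if (length(events) == 0) {
    return(tibble::tibble(person_a = character(), person_b = character(),
                          day = integer(), start_time = as.POSIXct(character(), tz = "UTC"),
                          duration_min = numeric(), distance_m = numeric()))
  }
  out <- dplyr::bind_rows(events)
  dur <- pmax(2, rlnorm(nrow(out), config$duration_meanlog, config$duration_sdlog))
  # events start between 07:00 and 21:00 and never cross midnight
  start_sec <- runif(nrow(out), 7 * 3600, 21 * 3600)
  dur <- pmin(dur, (24 * 3600 - start_sec) / 60 - 2)
  out$start_time <- as.POSIXct(config$trial_start, tz = "UTC") +
    (out$day - 1) * 86400 + round(start_sec)
  out$duration_min <- round(dur, 2)
  dplyr::arrange(
    dplyr::select(out, "person_a", "person_b", "day", "start_time",
                  "duration_min", "distance_m"),
    .data$day, .data$start_time, .data$person_a, .data$person_b
  )
}

draw_distances <- function(n, config) {
  band <- sample.int(3L, n, replace = TRUE, prob = config$distance_distribution)
  lower <- c(0, 1, 2)[band]
  upper <- c(1, 2, 4)[band]
  runif(n, lower, upper)
}

household_pairs <- function(population) {
  population |>
    dplyr::inner_join(population, by = "household_id",
                      suffix = c("_a", "_b"), relationship = "many-to-many") |>
    dplyr::filter(.data$participant_id_a < .data$participant_id_b) |>
    dplyr::transmute(person_a = .data$participant_id_a,
                     person_b = .data$participant_id_b,
                     household_id = .data$household_id)
}

#' Simulate wear compliance and household card-left-home artifacts
#'
#' Draws, for every participant and day, whether the card is actually worn
#' (probability `wear_prob_by_day[day]`), and for every multi-person
#' household and day whether the household left its cards co-located at home
#' (probability `p_household_card_left_home`). Members of a flagged
#' household-day do not wear their cards that day; instead their abandoned
#' cards see each other at point-blank range all day.
#'
#' @inheritParams generate_true_contacts
#' @return An object of class `wear_schedule`: a list with tibbles `wear`
#'   (`participant_id`, `day`, `worn`) and `households_left_home`
#'   (`household_id`, `day`).
#' @export
build_wear_schedule <- function(population, config) {
  validate_generator_config(config)
  local_generator_seed(config, 3L)
  days <- seq_len(config$n_days)
  wear <- tidyr::expand_grid(participant_id = population$participant_id, day = days)
  wear$worn <- rbinom(nrow(wear), 1L, config$wear_prob_by_day[wear$day]) == 1L

  hh_sizes <- dplyr::count(population, .data$household_id)
  multi <- hh_sizes$household_id[hh_sizes$n >= 2]
  flags <- tidyr::expand_grid(household_id = multi, day = days)
  flags <- flags[rbinom(nrow(flags), 1L, config$p_household_card_left_home) == 1L, ]

  if (nrow(flags) > 0) {
    flagged_members <- dplyr::inner_join(population, flags, by = "household_id",
                                         relationship = "many-to-many")
    wear <- wear |>
      dplyr::left_join(dplyr::mutate(flagged_members, left_home = TRUE),
                       by = c("participant_id", "day")) |>
      dplyr::mutate(worn = .data$worn & !dplyr::coalesce(.data$left_home, FALSE)) |>
      dplyr::select("participant_id", "day", "worn")
  }
  structure(list(wear = wear, households_left_home = flags),
            class = "wear_schedule")
}

#' Simulate raw RSSI reading streams from true contact events
#'
#' For every true contact event whose two participants both wear their cards
#' that day, emits two directed streams of 15-second scan readings covering
#' the event duration. Each reading follows the log-distance path-loss model
#' `RSSI = rssi_at_1m - 20 * log10(distance) + Normal(0, rssi_noise_sd)`,
#' rounded to integer dBm. Readings below the -62 dBm storage floor are still
#' emitted: discarding them is the card pipeline's job, not the radio's.
#'
#' Households flagged as having left their cards at home additionally emit a
#' full day of close-range readings between every pair of their cards,
#' producing the signature >= 22 h class-0 durations of non-compliance.
#'
#' @param events Output of [generate_true_contacts()].
#' @param wear_schedule Output of [build_wear_schedule()].
#' @param population Output of [generate_population()] (needed to resolve
#'   household membership for the card-left-home artifact).
#' @param config A [generator_config()].
#' @return A tibble of directed readings: `observer_id`, `observed_id`,
#'   `timestamp` (POSIXct, UTC), `rssi_dbm` (integer).
#' @export
simulate_rssi_stream <- function(events, wear_schedule, population, config) {
  validate_generator_config(config)
  stopifnot(inherits(wear_schedule, "wear_schedule"))
  known <- population$participant_id
  bad <- setdiff(unique(c(events$person_a, events$person_b)), known)
  if (length(bad) > 0) {
    stop("Events reference unknown participants: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  local_generator_seed(config, 4L)

  worn <- wear_schedule$wear
  lookup_worn <- function(id, day) {
    m <- match(paste(id, day), paste(worn$participant_id, worn$day))
    worn$worn[m]
  }
  ev <- events
  genuine <- NULL
  if (nrow(ev) > 0) {
    both <- lookup_worn(ev$person_a, ev$day) & lookup_worn(ev$person_b, ev$day)
    ev <- ev[both, , drop = FALSE]
  }
  if (nrow(ev) > 0) {
    n_slots <- pmax(1L, floor(ev$duration_min * 60 / 15))
    idx <- rep(seq_len(nrow(ev)), n_slots)
    offset <- unlist(lapply(n_slots, function(k) seq_len(k) - 1L)) * 15
    base <- tibble::tibble(
      a = ev$person_a[idx], b = ev$person_b[idx],
      timestamp = ev$start_time[idx] + offset,
      distance_m = ev$distance_m[idx]
    )
    genuine <- dplyr::bind_rows(
      tibble::tibble(observer_id = base$a, observed_id = base$b,
                     timestamp = base$timestamp, distance_m = base$distance_m),
      tibble::tibble(observer_id = base$b, observed_id = base$a,
                     timestamp = base$timestamp, distance_m = base$distance_m)
    )
  }

  left_home <- wear_schedule$households_left_home
  artifact <- NULL
  if (nrow(left_home) > 0) {
    pairs <- household_pairs(population) |>
      dplyr::inner_join(left_home, by = "household_id",
                        relationship = "many-to-many")
    if (nrow(pairs) > 0) {
      slots_per_day <- 86400L / 15L
      idx <- rep(seq_len(nrow(pairs)), each = slots_per_day)
      offs <- rep(seq_len(slots_per_day) - 1L, times = nrow(pairs)) * 15
      day0 <- as.POSIXct(config$trial_start, tz = "UTC") + (pairs$day[idx] - 1) * 86400
      base <- tibble::tibble(a = pairs$person_a[idx], b = pairs$person_b[idx],
                             timestamp = day0 + offs,
                             distance_m = 0.3)  # cards in a drawer together
      artifact <- dplyr::bind_rows(
        tibble::tibble(observer_id = base$a, observed_id = base$b,
                       timestamp = base$timestamp, distance_m = base$distance_m),
        tibble::tibble(observer_id = base$b, observed_id = base$a,
                       timestamp = base$timestamp, distance_m = base$distance_m)
      )
    }
  }

  out <- dplyr::bind_rows(genuine, artifact)
  if (is.null(out) || nrow(out) == 0) {
    return(tibble::tibble(observer_id = character(), observed_id = character(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          rssi_dbm = integer()))
  }
  out$rssi_dbm <- as.integer(round(
    config$rssi_at_1m - 20 * log10(out$distance_m) +
      rnorm(nrow(out), 0, config$rssi_noise_sd)
  ))
  # one scan per 15-s interval per directed pair: overlapping contact events
  # between the same two cards register as the strongest signal seen
  out |>
    dplyr::mutate(slot = floor(as.numeric(.data$timestamp) / 15)) |>
    dplyr::arrange(.data$observer_id, .data$observed_id, .data$slot,
                   dplyr::desc(.data$rssi_dbm)) |>
    dplyr::distinct(.data$observer_id, .data$observed_id, .data$slot,
                    .keep_all = TRUE) |>
    dplyr::select("observer_id", "observed_id", "timestamp", "rssi_dbm")
}

#' Simulate interview-based case-investigation reports
#'
#' Each interviewed participant independently recalls each of their true
#' contact events with probability `p_report`; a recalled event's date shifts
#' one day earlier or later with probability `p_date_shift` (uniform over the
#' two directions, clamped to the trial window). Repeated same-day contacts
#' with the same person collapse to a single report, keeping the longest
#' duration, mirroring interview protocols that record at most one contact
#' event per person per day.
#'
#' @param events Output of [generate_true_contacts()].
#' @param interviewed_ids Character vector of interviewed participant IDs.
#' @param config A [generator_config()].
#' @return A tibble of reports: `reporter_id`, `contact_id`, `day`, `date`,
#'   `duration_min`.
#' @export
simulate_case_reports <- function(events, interviewed_ids, config) {
  validate_generator_config(config)
  local_generator_seed(config, 5L)
  empty <- tibble::tibble(reporter_id = character(), contact_id = character(),
                          day = integer(), date = as.Date(character()),
                          duration_min = numeric())
  if (nrow(events) == 0 || length(interviewed_ids) == 0) return(empty)

  directed <- dplyr::bind_rows(
    dplyr::transmute(events, reporter_id = .data$person_a, contact_id = .data$person_b,
                     day = .data$day, duration_min = .data$duration_min),
    dplyr::transmute(events, reporter_id = .data$person_b, contact_id = .data$person_a,
                     day = .data$day, duration_min = .data$duration_min)
  ) |>
    dplyr::filter(.data$reporter_id %in% interviewed_ids) |>
    dplyr::arrange(.data$reporter_id, .data$day, .data$contact_id)
  if (nrow(directed) == 0) return(empty)

  recalled <- directed[runif(nrow(directed)) < config$p_report, , drop = FALSE]
  if (nrow(recalled) == 0) return(empty)

  shift_draw <- runif(nrow(recalled))
  shift <- ifelse(shift_draw < config$p_date_shift / 2, -1L,
                  ifelse(shift_draw < config$p_date_shift, 1L, 0L))
  recalled$day <- pmin(pmax(recalled$day + shift, 1L), config$n_days)

  recalled |>
    dplyr::group_by(.data$reporter_id, .data$contact_id, .data$day) |>
    dplyr::summarise(duration_min = max(.data$duration_min), .groups = "drop") |>
    dplyr::mutate(date = config$trial_start + .data$day - 1L) |>
    dplyr::select("reporter_id", "contact_id", "day", "date", "duration_min")
}

#' Run the full synthetic trial
#'
#' Convenience wrapper chaining population, true contacts, wear schedule,
#' RSSI streams, interviewed subset, and case reports.
#'
#' @param config A [generator_config()].
#' @return A list with elements `population`, `events`, `wear_schedule`,
#'   `readings`, `interviewed_ids`, `reports`, `config`.
#' @export
simulate_trial <- function(config = generator_config()) {
  validate_generator_config(config)
  population <- generate_population(config)
  events <- generate_true_contacts(population, config)
  wear_schedule <- build_wear_schedule(population, config)
  readings <- simulate_rssi_stream(events, wear_schedule, population, config)
  local_generator_seed(config, 6L)
  interviewed_ids <- sort(sample(population$participant_id, config$n_interviewed))
  reports <- simulate_case_reports(events, interviewed_ids, config)
  list(population = population, events = events, wear_schedule = wear_schedule,
       readings = readings, interviewed_ids = interviewed_ids,
       reports = reports, config = config)
}

#' Write synthetic trial outputs as CSV
#'
#' Raw readings use the schema `observer_id,observed_id,timestamp_iso8601,
#' rssi_dbm`; reports use `reporter_id,contact_id,date_iso8601,duration_min`;
#' truth files carry the full event table for evaluation.
#'
#' @param readings,reports,events Tibbles as produced by the generator.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_readings_csv <- function(readings, path) {
  out <- data.frame(
    observer_id = readings$observer_id,
    observed_id = readings$observed_id,
    timestamp_iso8601 = format(readings$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    rssi_dbm = readings$rssi_dbm
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_readings_csv
#' @export
write_reports_csv <- function(reports, path) {
  out <- data.frame(
    reporter_id = reports$reporter_id,
    contact_id = reports$contact_id,
    date_iso8601 = format(reports$date, "%Y-%m-%d"),
    duration_min = reports$duration_min
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_readings_csv
#' @export
write_truth_csv <- function(events, path) {
  out <- as.data.frame(events)
  out$start_time <- format(out$start_time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
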