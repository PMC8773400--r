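test_that("generator config validates probabilities and distributions", {
  expect_error(generator_config(n_participants = 1), "at least 2")
  expect_error(generator_config(household_size_distribution = c(0.5, 0.4)),
               "summing to 1")
  expect_error(generator_config(n_days = 3, wear_prob_by_day = c(1, 1)),
               "length")
  expect_error(generator_config(p_report = 1.2), "\\[0, 1\\]")
  expect_s3_class(generator_config(n_participants = 5, seed = 1),
                  "generator_config")
})

test_that("population generation respects household structure and seeding", {
  cfg <- generator_config(n_participants = 1191, seed = 11)
  pop <- generate_population(cfg)
  expect_equal(nrow(pop), 1191)
  expect_equal(anyDuplicated(pop$participant_id), 0)
  # every participant in exactly one household
  expect_true(all(table(pop$participant_id) == 1))

  # degenerate distribution: all singleton households
  cfg1 <- generator_config(n_participants = 2,
                           household_size_distribution = c(1, 0, 0, 0, 0, 0),
                           seed = 2)
  pop1 <- generate_population(cfg1)
  expect_equal(dplyr::n_distinct(pop1$household_id), 2)

  cfg7 <- generator_config(n_participants = 100, seed = 7)
  expect_identical(generate_population(cfg7), generate_population(cfg7))

  # household sizes track the configured distribution (large-sample check)
  cfg_big <- generator_config(n_participants = 6000, seed = 5,
                              household_size_distribution = c(0.2, 0.5, 0.3, 0, 0, 0))
  sizes <- dplyr::count(generate_population(cfg_big), household_id)$n
  expect_true(all(sizes %in% 1:3))
  expect_equal(mean(sizes == 2), 0.5, tolerance = 0.08)
})

test_that("true contact events respect rate, support and canonical order", {
  cfg0 <- tiny_config()
  cfg0$contact_rate <- 0
  expect_equal(nrow(generate_true_contacts(generate_population(cfg0), cfg0)), 0)

  cfg <- tiny_config()
  ev <- generate_true_contacts(generate_population(cfg), cfg)
  expect_true(all(ev$person_a < ev$person_b))
  expect_true(all(ev$duration_min >= 2))
  expect_true(all(ev$distance_m > 0 & ev$distance_m <= 4))
  expect_true(all(ev$day %in% 1:3))

  # Monte-Carlo check of the community contact rate (no household events)
  rates <- vapply(1:60, function(s) {
    cfg_s <- generator_config(n_participants = 100, n_days = 5, n_interviewed = 0,
                              household_size_distribution = c(1, 0, 0, 0, 0, 0),
                              contact_rate = 2, household_contact_rate = 0,
                              wear_prob_by_day = rep(1, 5), seed = 1000 + s)
    ev_s <- generate_true_contacts(generate_population(cfg_s), cfg_s)
    2 * nrow(ev_s) / (100 * 5)   # each event touches two participants
  }, 0)
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 2), 3 * se + 1e-12)
})

test_that("noiseless RSSI recovers the path-loss calibration and class bands", {
  cfg <- tiny_config()
  pop <- generate_population(cfg)
  ws <- build_wear_schedule(pop, cfg)
  ev <- tibble::tibble(person_a = "P0001", person_b = "P0002", day = 1L,
                       start_time = as.POSIXct("2020-11-09 10:00:00", tz = "UTC"),
                       duration_min = 4, distance_m = 1)
  rd <- simulate_rssi_stream(ev, ws, pop, cfg)
  expect_true(all(rd$rssi_dbm == -50L))
  expect_equal(nrow(rd), 2 * 16)   # two directions, 15-s cadence
  expect_equal(diff(as.numeric(sort(unique(rd$timestamp)))), rep(15, 15))

  ev$distance_m <- 2
  expect_true(all(simulate_rssi_stream(ev, ws, pop, cfg)$rssi_dbm == -56L))

  # table of class boundaries recovered at representative distances
  for (case in list(list(d = 0.5, class = 0L), list(d = 1.5, class = 1L),
                    list(d = 3, class = 2L))) {
    ev$distance_m <- case$d
    cls <- classify_proximity(simulate_rssi_stream(ev, ws, pop, cfg)$rssi_dbm)
    expect_true(all(cls == case$class), info = sprintf("distance %.1f", case$d))
  }

  # both participants non-compliant: no readings
  ws$wear$worn[ws$wear$participant_id %in% c("P0001", "P0002")] <- FALSE
  ev$distance_m <- 1
  expect_equal(nrow(simulate_rssi_stream(ev, ws, pop, cfg)), 0)

  bad <- ev
  bad$person_b <- "GHOST"
  expect_error(simulate_rssi_stream(bad, ws, pop, cfg), "unknown participant")
})

test_that("household card-left-home artifact emits a full day of class-0 signal", {
  cfg <- generator_config(n_participants = 4, n_days = 2, n_interviewed = 0,
                          household_size_distribution = c(0, 1, 0, 0, 0, 0),
                          contact_rate = 0, household_contact_rate = 0,
                          wear_prob_by_day = c(1, 1),
                          p_household_card_left_home = 1,
                          rssi_noise_sd = 0, seed = 9)
  pop <- generate_population(cfg)
  ws <- build_wear_schedule(pop, cfg)
  expect_equal(nrow(ws$households_left_home), 2 * 2)  # both households, both days
  expect_true(all(!ws$wear$worn))                     # cards stayed home

  empty_events <- generate_true_contacts(pop, cfg)
  rd <- simulate_rssi_stream(empty_events, ws, pop, cfg)
  daily <- aggregate_daily(aggregate_two_hour(build_two_minute_records(rd)))
  expect_true(all(daily$min_class0 == 1440))          # a full co-located day
  expect_true(all(daily$min_class1 == 0 & daily$min_class2 == 0))
  expect_gte(min(daily$min_class0), 22 * 60)          # the >= 22 h signature
})

test_that("case reports implement recall, date shifts and same-day collapse", {
  cfg <- tiny_config()
  pop <- generate_population(cfg)
  ev <- generate_true_contacts(pop, cfg)
  interviewed <- pop$participant_id[1:6]

  # perfect recall: every event of an interviewed participant appears, dates exact
  rep1 <- simulate_case_reports(ev, interviewed, cfg)
  truth <- dplyr::bind_rows(
    dplyr::transmute(ev, reporter_id = person_a, contact_id = person_b, day = day),
    dplyr::transmute(ev, reporter_id = person_b, contact_id = person_a, day = day)
  ) |>
    dplyr::filter(reporter_id %in% interviewed) |>
    dplyr::distinct() |>
    dplyr::arrange(reporter_id, contact_id, day)
  expect_identical(dplyr::arrange(rep1[, c("reporter_id", "contact_id", "day")],
                                  reporter_id, contact_id, day),
                   truth)
  expect_true(all(rep1$duration_min >= 2))
  # at most one report per (reporter, contact, day)
  expect_equal(anyDuplicated(rep1[, c("reporter_id", "contact_id", "day")]), 0)

  cfg0 <- tiny_config()
  cfg0$p_report <- 0
  expect_equal(nrow(simulate_case_reports(ev, interviewed, cfg0)), 0)

  # date shifts stay clamped inside the trial window
  cfg_shift <- tiny_config()
  cfg_shift$p_date_shift <- 1
  rep_s <- simulate_case_reports(ev, interviewed, cfg_shift)
  expect_true(all(rep_s$day >= 1 & rep_s$day <= cfg_shift$n_days))
})

test_that("report-network reciprocity converges to the recall probability", {
  # 500 disjoint dyads, both members interviewed, one true event each:
  # mutual w.p. p^2, asymmetric w.p. 2p(1-p), so r = p.
  p <- 0.7
  n_dyads <- 500
  ids <- sprintf("P%04d", 1:(2 * n_dyads))
  ev <- tibble::tibble(
    person_a = ids[seq(1, length(ids), 2)], person_b = ids[seq(2, length(ids), 2)],
    day = 1L, start_time = as.POSIXct("2020-11-09 10:00:00", tz = "UTC"),
    duration_min = 10, distance_m = 1
  )
  cfg <- generator_config(n_participants = 2 * n_dyads, n_days = 1,
                          n_interviewed = 2 * n_dyads,
                          wear_prob_by_day = 1, p_report = p, p_date_shift = 0,
                          seed = 77)
  reports <- simulate_case_reports(ev, ids, cfg)
  edges <- build_reported_dyads(reports, ids)
  est <- reciprocity_r(dyad_census(edges, ids))
  expect_lt(abs(est$r - p), 2 * sqrt(p * (1 - p) / est$n_edges) + 0.02)
})

test_that("card-network reciprocity tracks the per-direction detection rate", {
  # 500 disjoint dyads, all cards worn, one 10-min event each. Each direction
  # is detected independently (independent RSSI noise), so the day-level card
  # network has r equal to the per-direction detection probability, which is
  # estimated directly from the directed daily records themselves.
  n_dyads <- 500
  ids <- sprintf("P%04d", 1:(2 * n_dyads))
  ev <- tibble::tibble(
    person_a = ids[seq(1, length(ids), 2)], person_b = ids[seq(2, length(ids), 2)],
    day = 1L, start_time = as.POSIXct("2020-11-09 10:00:00", tz = "UTC"),
    duration_min = 10, distance_m = 3.5
  )
  pop <- tibble::tibble(participant_id = ids,
                        household_id = sprintf("H%04d", seq_along(ids)))
  # noise makes some windows fail the -62 dBm floor at 3.5 m (true RSSI -60.9)
  cfg <- generator_config(n_participants = 2 * n_dyads, n_days = 1,
                          n_interviewed = 0, wear_prob_by_day = 1,
                          p_household_card_left_home = 0, rssi_noise_sd = 3,
                          seed = 61)
  ws <- build_wear_schedule(pop, cfg)
  daily <- aggregate_daily(aggregate_two_hour(build_two_minute_records(
    simulate_rssi_stream(ev, ws, pop, cfg))))

  # noiseless control first: every direction detected, r exactly 1
  cfg0 <- cfg
  cfg0$rssi_noise_sd <- 0
  daily0 <- aggregate_daily(aggregate_two_hour(build_two_minute_records(
    simulate_rssi_stream(ev, ws, pop, cfg0))))
  cc0 <- dyad_census(tibble::tibble(from = daily0$observer_id,
                                    to = daily0$observed_id), ids)
  expect_equal(reciprocity_r(cc0)$r, 1)

  p_hat <- nrow(daily) / (2 * n_dyads)       # directed detections per direction
  cc <- dyad_census(tibble::tibble(from = daily$observer_id,
                                   to = daily$observed_id), ids)
  est <- reciprocity_r(cc)
  expect_gt(p_hat, 0.05)
  expect_lt(p_hat, 0.95)
  expect_lt(abs(est$r - p_hat), 2 * sqrt(p_hat * (1 - p_hat) / est$n_edges) + 0.03)
})

test_that("zero-interaction fraction recovers wear non-compliance", {
  # n test subjects each paired with a partner forced compliant; the fraction
  # of subjects with no readings on day d estimates 1 - wear_prob_by_day[d].
  n <- 300
  ids <- sprintf("P%04d", 1:(2 * n))
  subjects <- ids[seq(1, length(ids), 2)]
  partners <- ids[seq(2, length(ids), 2)]
  wear_p <- c(0.9, 0.6)
  cfg <- generator_config(n_participants = 2 * n, n_days = 2, n_interviewed = n,
                          household_size_distribution = c(1, 0, 0, 0, 0, 0),
                          contact_rate = 0, household_contact_rate = 0,
                          wear_prob_by_day = wear_p, p_household_card_left_home = 0,
                          rssi_noise_sd = 0, seed = 31)
  pop <- tibble::tibble(participant_id = ids,
                        household_id = sprintf("H%04d", seq_along(ids)))
  ev <- tidyr::expand_grid(idx = seq_len(n), day = 1:2)
  ev <- tibble::tibble(
    person_a = subjects[ev$idx], person_b = partners[ev$idx], day = as.integer(ev$day),
    start_time = as.POSIXct("2020-11-09 10:00:00", tz = "UTC") + (ev$day - 1) * 86400,
    duration_min = 10, distance_m = 1
  )
  ws <- build_wear_schedule(pop, cfg)
  ws$wear$worn[ws$wear$participant_id %in% partners] <- TRUE
  rd <- simulate_rssi_stream(ev, ws, pop, cfg)
  for (d in 1:2) {
    day_ids <- unique(rd$observer_id[as.Date(rd$timestamp) == cfg$trial_start + d - 1])
    frac_zero <- mean(!subjects %in% day_ids)
    p0 <- 1 - wear_p[d]
    expect_lt(abs(frac_zero - p0), 2 * sqrt(p0 * (1 - p0) / n) + 0.02)
  }
})

test_that("the full synthetic trial is bit-reproducible and round-trips CSV", {
  cfg <- generator_config(n_participants = 30, n_days = 3, n_interviewed = 8,
                          contact_rate = 0.5, p_household_card_left_home = 0.2,
                          wear_prob_by_day = c(0.9, 0.8, 0.7), seed = 123)
  t1 <- simulate_trial(cfg)
  t2 <- simulate_trial(cfg)
  expect_identical(t1$readings, t2$readings)
  expect_identical(t1$reports, t2$reports)
  expect_identical(t1$interviewed_ids, t2$interviewed_ids)

  tmp <- withr::local_tempfile(fileext = ".csv")
  write_readings_csv(t1$readings, tmp)
  back <- read_readings_csv(tmp)
  expect_equal(nrow(back), nrow(t1$readings))
  expect_identical(back$rssi_dbm, t1$readings$rssi_dbm)
  expect_equal(as.numeric(back$timestamp), as.numeric(t1$readings$timestamp))

  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_reports_csv(t1$reports, tmp2)
  back2 <- read_reports_csv(tmp2)
  expect_identical(back2$reporter_id, t1$reports$reporter_id)
  expect_identical(back2$date, t1$reports$date)

  tmp3 <- withr::local_tempfile(fileext = ".yaml")
  write_generator_config(cfg, tmp3)
  expect_equal(unclass(read_generator_config(tmp3)), unclass(cfg))
})
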