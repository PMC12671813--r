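test_that("event threshold derives from the red-muscle limit", {
  thr <- physio_thresholds()
  expect_equal(thr$t_event_C, 35 - 4)
  expect_equal(thr$t_event_C, 31)
  expect_error(physio_thresholds(t_spawn_C = 40))
})

test_that("daily thermal summary aggregates mean water and max body", {
  s <- fixture_flat_series(n_days = 2, temp = 20)
  d <- daily_thermal_summary(s)
  expect_equal(d$mean_water_C, c(20, 20))
  expect_equal(d$max_body_C, c(20, 20))
  # independent re-aggregation oracle on simulated data
  f <- fixture_field()
  tr <- simulate_track(c(36, 141), as.Date("2021-06-01"), 4, "resident",
                       seed = 41)
  sim <- simulate_sensor_series(tr, f, seed = 42)
  got <- daily_thermal_summary(sim$series)
  day <- as.Date(sim$series$timestamp_utc, tz = "UTC")
  expect_equal(got$mean_water_C,
               as.numeric(tapply(sim$series$temp_external_c, day, mean)),
               tolerance = 1e-9)
  expect_equal(got$max_body_C,
               as.numeric(tapply(sim$series$temp_internal_c, day, max)),
               tolerance = 1e-9)
  expect_true(all(got$max_body_C >=
                    tapply(sim$series$temp_internal_c, day, mean)))
})

test_that("an implanted event dominates its day's body maximum", {
  f <- fixture_field()
  tr <- simulate_track(c(24, 135), as.Date("2021-07-01"), 8, "resident",
                       seed = 43)
  sim <- simulate_sensor_series(tr, f, event_params = list(n_events = 2),
                                seed = 44)
  d <- daily_thermal_summary(sim$series)
  event_days <- unique(as.Date(sim$events$crossing_utc, tz = "UTC"))
  expect_true(all(d$max_body_C[d$date %in% event_days] >= 31))
})

test_that("monthly summaries pool individuals and flag thresholds", {
  s <- fixture_flat_series(n_days = 28, temp = 20,
                           start = as.POSIXct("2021-02-01", tz = "UTC"))
  m <- monthly_experienced(list(daily_thermal_summary(s)), "residence")
  expect_equal(m$mean_C, 20)
  expect_equal(m$sd_C, 0)
  expect_true(m$below_spawn)
  expect_false(m$at_lethal_limit)
})

test_that("UPGMA separates well-separated clouds", {
  pts <- rbind(c(0, 0), c(0.1, 0), c(10, 10), c(10.1, 10))
  expect_equal(agglomerative_cluster(pts, 2), c(1, 1, 2, 2))
  expect_error(agglomerative_cluster(pts[1, , drop = FALSE], 2), "fewer")
  # thermal-trait style clouds: (max body, mean water)
  withr::with_seed(45, {
    warm <- cbind(rnorm(150, 29, 1), rnorm(150, 26, 1))
    cool <- cbind(rnorm(150, 24, 1), rnorm(150, 19, 1))
  })
  lab <- agglomerative_cluster(rbind(warm, cool), 2)
  truth <- rep(1:2, each = 150)
  expect_gte(max(mean(lab == truth), mean(lab == 3 - truth)), 0.95)
})

test_that("UPGMA matches the reference implementation exactly", {
  for (s in 1:12) {
    withr::with_seed(s, {
      pts <- cbind(runif(120, 0, 10), runif(120, 0, 10))
    })
    lab <- agglomerative_cluster(pts, 2)
    ref <- stats::cutree(stats::hclust(stats::dist(pts),
                                       method = "average"), 2)
    expect_equal(max(mean(lab == ref), mean(lab == 3 - ref)), 1)
  }
})

test_that("UPGMA labels are invariant to point order up to swap", {
  withr::with_seed(46, {
    pts <- cbind(runif(60), runif(60))
    perm <- sample(60)
  })
  l1 <- agglomerative_cluster(pts, 2)
  l2 <- agglomerative_cluster(pts[perm, ], 2)
  expect_equal(max(mean(l2 == l1[perm]), mean(l2 == 3 - l1[perm])), 1)
})

test_that("event detection applies threshold, merge and duration rules", {
  base <- fixture_flat_series(n_days = 1, temp = 25)
  expect_equal(nrow(detect_thermal_events(base)), 0)
  # two excursions separated by a 3-minute dip merge into one event
  s <- base
  i0 <- 1000
  s$temp_internal_c[i0:(i0 + 20)] <- 31.5
  s$temp_internal_c[(i0 + 27):(i0 + 47)] <- 31.5
  ev <- detect_thermal_events(s, merge_gap_min = 10)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$end_utc, s$timestamp_utc[i0 + 47])
  # with a tiny merge gap they stay separate
  ev2 <- detect_thermal_events(s, merge_gap_min = 1)
  expect_equal(nrow(ev2), 2)
  # single-sample blips are discarded by the duration guard
  s3 <- base
  s3$temp_internal_c[500] <- 31.5
  expect_equal(nrow(detect_thermal_events(s3, min_duration_min = 1)), 0)
})

test_that("lowering the event threshold never removes events", {
  # cooler water keeps the baseline well under both thresholds, so the
  # comparison probes the detector, not baseline saturation
  f <- fixture_field()
  tr <- simulate_track(c(33, 141), as.Date("2021-07-01"), 15, "resident",
                       seed = 47)
  sim <- simulate_sensor_series(tr, f, event_params = list(n_events = 6),
                                seed = 48)
  n31 <- nrow(detect_thermal_events(sim$series))
  n30 <- nrow(detect_thermal_events(
    sim$series, physio_thresholds(gradient_rm_peritoneal_C = 5)
  ))
  expect_gte(n30, n31)
})

test_that("event detection is invariant to prepending event-free data", {
  f <- fixture_field()
  tr <- simulate_track(c(24, 135), as.Date("2021-07-03"), 6, "resident",
                       seed = 49)
  sim <- simulate_sensor_series(tr, f, event_params = list(n_events = 3),
                                seed = 50)
  ev1 <- detect_thermal_events(sim$series)
  quiet <- fixture_flat_series(
    n_days = 2, temp = 25,
    start = as.POSIXct("2021-07-01", tz = "UTC")
  )
  ev2 <- detect_thermal_events(dplyr::bind_rows(quiet, sim$series))
  expect_equal(ev2$crossing_utc, ev1$crossing_utc)
  expect_equal(ev2$onset_utc, ev1$onset_utc)
  # every event satisfies the ordering invariants
  expect_true(all(ev1$onset_utc <= ev1$crossing_utc))
  expect_true(all(ev1$crossing_utc <= ev1$peak_utc))
  expect_true(all(ev1$peak_utc <= ev1$end_utc))
  expect_true(all(ev1$peak_C >= 31))
})

test_that("onset tracing handles ramps and steps", {
  ts <- seq(as.POSIXct("2021-01-01", tz = "UTC"), by = 30,
            length.out = 2880)
  ramp <- 70 # samples = 35 minutes
  i0 <- 1000
  temp <- rep(28, 2880)
  temp[i0:(i0 + ramp)] <- 28 + (31.5 - 28) * (0:ramp) / ramp
  temp[(i0 + ramp):(i0 + ramp + 30)] <- 31.5
  s <- tibble::tibble(timestamp_utc = ts, depth_m = 1,
                      temp_internal_c = temp, temp_external_c = 20,
                      light = 0)
  ev <- detect_thermal_events(s)
  expect_lte(abs(as.numeric(ev$onset_utc[1] - ts[i0], units = "secs")), 30)
  # instantaneous step: onset coincides with the crossing
  temp2 <- rep(28, 2880)
  temp2[1500:1560] <- 32
  s2 <- s
  s2$temp_internal_c <- temp2
  ev2 <- detect_thermal_events(s2)
  expect_lte(abs(as.numeric(ev2$onset_utc[1] - ev2$crossing_utc[1],
                            units = "secs")), 30)
})

test_that("inter-event intervals and onset histogram add up", {
  ev <- tibble::tibble(
    onset_utc = as.POSIXct("2021-07-01", tz = "UTC") +
      c(0, 2, 3) * 86400,
    onset_local_solar_hour = c(15.5, 15.6, 15.9)
  )
  iv <- event_interval_stats(ev)
  expect_equal(sort(iv$intervals_days), c(1, 2))
  expect_equal(unname(iv$summary["max"]), 2)
  expect_length(event_interval_stats(ev[1, ])$intervals_days, 0)
  h <- onset_hour_histogram(ev)
  expect_equal(sum(h), 3)
  expect_equal(unname(h["15"]), 3L)
})

test_that("simulated event intervals respect the generator contract", {
  f <- fixture_field()
  tr <- simulate_track(c(24, 135), as.Date("2021-06-20"), 40, "resident",
                       seed = 51)
  sim <- simulate_sensor_series(tr, f, event_params = list(),
                                seed = 52)
  ev <- detect_thermal_events(sim$series, track = tr)
  iv <- event_interval_stats(ev)
  expect_true(all(iv$intervals_days >= 0.5 & iv$intervals_days <= 3.5))
  h <- onset_hour_histogram(ev)
  expect_true(as.integer(names(which.max(h))) %in% 14:18)
})
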