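test_that("solar geometry matches published anchor values", {
  eq <- solar_geometry(as.Date("2021-03-20"))
  expect_lt(abs(eq$declination_deg), 1)
  sol <- solar_geometry(as.Date("2021-06-21"))
  expect_equal(sol$declination_deg, 23.44, tolerance = 0.2 / 23.44)
  nov <- solar_geometry(as.Date("2021-11-03"))
  expect_gte(nov$equation_of_time_min, 14)
  expect_lte(nov$equation_of_time_min, 17)
  expect_true(all(abs(solar_geometry(as.Date("2021-01-01") +
                                       0:364)$declination_deg) <= 23.5))
})

test_that("twilight detection recovers astronomical day length", {
  tr <- tibble::tibble(date = as.Date("2021-06-18") + 0:5,
                       lat = 35, lon = 140, behavior = "resident")
  f <- fixture_field()
  sim <- simulate_sensor_series(tr, f, seed = 4)
  tw <- detect_twilights(sim$series, 0.3, 10)
  expect_gte(nrow(tw), 4)
  alt <- light_threshold_alt(0.3)
  dl <- as.numeric(tw$dusk_utc - tw$dawn_utc, units = "hours")
  astro <- day_length_hours(tw$date, 35, alt)
  expect_lt(max(abs(dl - astro)) * 60, 10)
})

test_that("constant light yields no twilights, with a warning per day", {
  s <- fixture_flat_series(n_days = 2)
  s$light <- 0
  w <- testthat::capture_warnings(tw <- detect_twilights(s, 0.3))
  expect_equal(nrow(tw), 0)
  expect_length(w, length(unique(as.Date(s$timestamp_utc, tz = "UTC"))))
})

test_that("dives shorter than the smoothing window leave twilights alone", {
  s <- fixture_flat_series(n_days = 3)
  tw0 <- detect_twilights(s, 0.3, 10)
  s2 <- s
  # 3-minute midday light dropouts (deep dives), well inside the window
  for (day in 0:2) {
    i0 <- which(abs(as.numeric(s2$timestamp_utc -
                                 (s2$timestamp_utc[1] + day * 86400 +
                                    3 * 3600), units = "secs")) < 90)
    i0 <- i0[1]
    s2$light[i0:(i0 + 5)] <- 1e-6
  }
  tw2 <- detect_twilights(s2, 0.3, 10)
  expect_equal(tw2$dawn_utc, tw0$dawn_utc)
  expect_equal(tw2$dusk_utc, tw0$dusk_utc)
})

test_that("template fit turns local noon into longitude", {
  dawn <- as.POSIXct("2021-05-10 06:00:00", tz = "UTC")
  dusk <- as.POSIXct("2021-05-10 18:00:00", tz = "UTC")
  # noon at 12:00 UTC with the equation of time removed -> lon 0
  est <- template_fit_position(dawn, dusk, as.Date("2021-05-10"))
  eot_h <- solar_geometry(as.Date("2021-05-10"))$equation_of_time_min / 60
  expect_equal(est$lon_light, 0 - 15 * eot_h, tolerance = 1e-6)
  # noon at 02:36 UTC -> 141 E (up to the same correction)
  dawn2 <- as.POSIXct("2021-05-10 20:36:00", tz = "UTC") - 86400
  dusk2 <- as.POSIXct("2021-05-10 08:36:00", tz = "UTC")
  est2 <- template_fit_position(dawn2, dusk2, as.Date("2021-05-10"))
  expect_equal(est2$lon_light, 141 - 15 * eot_h, tolerance = 1e-6)
  expect_error(template_fit_position(dusk, dawn), "dawn")
})

test_that("template-fit latitude is invalid in the equinox window", {
  d <- as.Date("2021-03-20") # |declination| < 3 degrees
  for (day_h in c(10, 12, 14)) {
    dawn <- as.POSIXct(paste(d, "06:00:00"), tz = "UTC")
    est <- template_fit_position(dawn, dawn + day_h * 3600, d)
    expect_false(est$lat_valid)
    expect_equal(est$obs_sd_lat, 20)
  }
  # away from the equinox the sunrise equation inverts exactly
  d2 <- as.Date("2021-06-21")
  decl <- solar_geometry(d2)$declination_deg
  for (lat_true in c(-35, 10, 35, 50)) {
    day_h <- day_length_hours(d2, lat_true)
    dawn <- as.POSIXct(paste(d2, "01:00:00"), tz = "UTC")
    est <- template_fit_position(dawn, dawn + day_h * 3600, d2)
    expect_true(est$lat_valid)
    expect_equal(est$lat_light, lat_true, tolerance = 1e-4)
  }
})

test_that("daily tag SST averages only shallow samples", {
  s <- fixture_flat_series(n_days = 1)
  s$depth_m <- rep(c(2, 10), length.out = nrow(s))
  s$temp_external_c <- ifelse(s$depth_m <= 5, 20, 25)
  out <- tag_sst_daily(s)
  expect_equal(out$sst_c, 20)
  expect_equal(out$n_samples, sum(s$depth_m <= 5))
  # brute-force group-by oracle on a simulated series
  f <- fixture_field()
  tr <- simulate_track(c(36, 141), as.Date("2021-06-01"), 5, "resident",
                       seed = 21)
  sim <- simulate_sensor_series(tr, f, seed = 22)
  got <- tag_sst_daily(sim$series)
  ss <- sim$series[sim$series$depth_m <= 5, ]
  want <- tapply(ss$temp_external_c, as.Date(ss$timestamp_utc, tz = "UTC"),
                 mean)
  expect_equal(got$sst_c, as.numeric(want), tolerance = 1e-9)
})

test_that("the smoother recovers a noiseless track", {
  tr <- simulate_track(c(36, 145), as.Date("2021-06-01"), 12, "resident",
                       seed = 23)
  raw <- simulate_raw_estimates(tr, obs_sd_lon = 0.05, obs_sd_lat = 0.05,
                                seed = 24)
  raw$lon_light <- tr$lon
  raw$lat_light <- tr$lat
  tk <- refine_track(raw, NULL, NULL,
                     list(sigma_kms = 15, init_latlon = c(36, 145)))
  expect_lt(max(abs(tk$lat - tr$lat)), 0.1)
  expect_lt(max(abs(tk$lon - tr$lon)), 0.1)
})

test_that("smoothing never loses information relative to filtering", {
  tr <- simulate_track(c(38, 150), as.Date("2021-09-01"), 60, "migrant",
                       seed = 25)
  f <- fixture_field()
  raw <- simulate_raw_estimates(tr, seed = 26)
  sst <- tibble::tibble(
    date = tr$date,
    sst_c = sst_lookup(f, tr$date, tr$lat, tr$lon) + 0.1
  )
  tk <- refine_track(raw, sst, f, list(init_latlon = c(38, 150)))
  expect_true(all(tk$sd_lat <= tk$sd_lat_filter + 1e-9))
  expect_true(all(tk$sd_lon <= tk$sd_lon_filter + 1e-9))
  # ML process noise fits no worse than the search bounds
  ll <- attr(tk, "log_lik")
  for (sig in c(10, 300)) {
    tk2 <- refine_track(raw, sst, f,
                        list(init_latlon = c(38, 150), sigma_kms = sig))
    expect_gte(ll, attr(tk2, "log_lik") - 1e-6)
  }
})

test_that("longitude estimates are unbiased on synthetic data", {
  tr <- simulate_track(c(36, 145), as.Date("2021-05-01"), 120, "resident",
                       seed = 27)
  f <- fixture_field()
  raw <- simulate_raw_estimates(tr, seed = 28)
  sst <- tibble::tibble(
    date = tr$date,
    sst_c = sst_lookup(f, tr$date, tr$lat, tr$lon)
  )
  tk <- refine_track(raw, sst, f, list(init_latlon = c(36, 145)))
  bias <- mean(tk$lon - tr$lon[match(tk$date, tr$date)])
  expect_lt(abs(bias), 0.2)
})

test_that("refine_track rejects unusable inputs", {
  raw <- simulate_raw_estimates(
    simulate_track(c(36, 145), Sys.Date(), 2, "resident", seed = 1),
    seed = 2
  )
  expect_error(refine_track(raw[1:2, ], NULL, NULL), ">= 3 days")
})

test_that("grid filter agrees with the unscented smoother", {
  tr <- simulate_track(c(38, 150), as.Date("2021-09-01"), 50, "migrant",
                       seed = 29)
  f <- fixture_field()
  raw <- simulate_raw_estimates(tr, seed = 30)
  withr::with_seed(31, {
    sst <- tibble::tibble(
      date = tr$date,
      sst_c = sst_lookup(f, tr$date, tr$lat, tr$lon) +
        stats::rnorm(nrow(tr), 0, 0.3)
    )
  })
  g <- grid_filter_oracle(raw, sst, f, grid_resolution_deg = 1,
                          sigma_kms = 100)
  u <- refine_track(raw, sst, f,
                    list(init_latlon = c(38, 150), sigma_kms = 100))
  agree <- mean(abs(g$lat - u$lat) <= 2 & abs(g$lon - u$lon) <= 2)
  expect_gte(agree, 0.9)
})

test_that("grid filter limits: noiseless pin-down and no-information spread", {
  tr <- simulate_track(c(36, 145), as.Date("2021-06-01"), 10, "resident",
                       seed = 32)
  raw <- simulate_raw_estimates(tr, obs_sd_lon = 0.05, obs_sd_lat = 0.05,
                                seed = 33)
  raw$lon_light <- tr$lon
  raw$lat_light <- tr$lat
  g <- grid_filter_oracle(raw, NULL, NULL, grid_resolution_deg = 0.5,
                          sigma_kms = 15)
  expect_lt(max(abs(g$lat - tr$lat)), 0.5)
  expect_lt(max(abs(g$lon - tr$lon)), 0.5)
  # uninformative observations: posterior spread grows from the release
  raw2 <- raw
  raw2$obs_sd_lat <- 1e6
  raw2$obs_sd_lon <- 1e6
  raw2$obs_sd_lat[1] <- 0.5
  raw2$obs_sd_lon[1] <- 0.5
  g2 <- grid_filter_oracle(raw2, NULL, NULL, grid_resolution_deg = 1,
                           lat_range = c(20, 50), lon_range = c(130, 160),
                           sigma_kms = 50)
  expect_true(all(diff(g2$sd_lat) > -1e-9))
})
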