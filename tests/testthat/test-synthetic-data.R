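test_that("simulated SST field anchors to its closed form", {
  f <- simulate_sst_field(
    dates = as.Date("2021-02-15") + 0:2,
    seasonal_amp_C = 0, noise_sd_C = 0, base_C = 24.5,
    lat_gradient_C_per_deg = 0.5
  )
  d <- as.Date("2021-02-15")
  expect_equal(sst_lookup(f, d, 30, 140), 24.5)
  expect_equal(sst_lookup(f, d, 40, 140) - sst_lookup(f, d, 30, 140), -5)
  # bilinear interpolation between grid nodes
  expect_equal(sst_lookup(f, d, 32.5, 140.5), 24.5 - 0.5 * 2.5)
})

test_that("default field reproduces the seasonal range at 36N", {
  f <- fixture_field()
  feb <- sst_lookup(f, seq(as.Date("2021-02-01"), as.Date("2021-02-28"),
                           by = "day"), 36, 141)
  jul <- sst_lookup(f, seq(as.Date("2021-07-01"), as.Date("2021-07-31"),
                           by = "day"), 36, 141)
  expect_lt(min(feb), 18)
  expect_gt(max(jul), 24)
  # tropical plateau: low latitudes saturate rather than overheating
  expect_lte(sst_lookup(f, as.Date("2021-08-15"), 5, 141), 30)
})

test_that("field generation errors on degenerate inputs", {
  expect_error(simulate_sst_field(dates = as.Date(character())), "empty")
  expect_error(
    simulate_sst_field(dates = Sys.Date(), lat_gradient_C_per_deg = 0),
    "nonzero"
  )
})

test_that("field round-trips through long-format CSV", {
  f <- simulate_sst_field(
    dates = as.Date("2021-03-01") + 0:1,
    lat_range = c(30, 33), lon_range = c(140, 143), seed = 4
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_sst_csv(f, path)
  g <- read_sst_csv(path)
  expect_equal(g$lat, f$lat)
  expect_equal(g$sst, f$sst, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("track advance matches the spherical formula", {
  # 111.195 km due south in one day is one degree of latitude
  tr <- simulate_track(c(35, 140), as.Date("2021-10-25"), 1, "migrant",
                       step_params = list(mean_km = 111.195, sd_km = 0,
                                          kappa = 1e9),
                       seed = 2)
  expect_equal(nrow(tr), 2)
  expect_equal(tr$lat[2] - tr$lat[1], -1, tolerance = 1e-3)
  expect_equal(tr$lon[2], tr$lon[1], tolerance = 1e-6)
})

test_that("resident tracks reproduce their own step distribution", {
  tr <- simulate_track(c(36.7, 141.4), as.Date("2021-10-25"), 200,
                       "resident", seed = 3)
  st <- daily_steps(tr)
  expect_equal(mean(st$distance_km), 34.6, tolerance = 5 / 34.6)
  expect_true(all(st$distance_km <= 300))
  expect_true(all(tr$lat >= -30 & tr$lat <= 55))
})

test_that("migrant tracks head south on average", {
  tr <- simulate_track(c(38, 150), as.Date("2021-09-01"), 150, "migrant",
                       seed = 4)
  expect_lt(tr$lat[151], tr$lat[1] - 10)
  st <- daily_steps(tr)
  expect_equal(mean(st$distance_km), 77, tolerance = 10 / 77)
})

test_that("track simulation rejects bad step parameters", {
  expect_error(
    simulate_track(c(35, 140), Sys.Date(), 5, "resident",
                   step_params = list(mean_km = -1)),
    "nonpositive"
  )
  expect_error(simulate_track(c(35, 140), Sys.Date(), 0, "resident"))
})

test_that("sensor series: no events means internal tracks external", {
  f <- fixture_field()
  tr <- simulate_track(c(36, 141), as.Date("2021-06-01"), 2, "resident",
                       seed = 5)
  sim <- simulate_sensor_series(tr, f, thermal_excess_C = 0,
                                event_params = NULL, seed = 6)
  d <- sim$series$temp_internal_c - sim$series$temp_external_c
  # two independent 0.1 C noise streams; 5 sigma bound on the max
  expect_lt(max(abs(d)), 5 * sqrt(2) * 0.1)
  expect_equal(nrow(sim$events), 0)
})

test_that("implanted events hold the plateau above threshold", {
  f <- fixture_field()
  tr <- simulate_track(c(24, 135), as.Date("2021-07-01"), 10, "resident",
                       seed = 7)
  sim <- simulate_sensor_series(tr, f, event_params = list(n_events = 4),
                                seed = 8)
  expect_gt(nrow(sim$events), 0)
  for (k in seq_len(nrow(sim$events))) {
    i1 <- which(sim$series$timestamp_utc == sim$events$crossing_utc[k])
    i2 <- which(sim$series$timestamp_utc == sim$events$end_utc[k])
    run <- sim$series$temp_internal_c[i1:i2]
    # plateau (15 min) plus the rise to peak: >= 30 consecutive samples
    expect_gte(sum(run >= 31), 15 * 60 / 30)
  }
})

test_that("light is dark at local midnight and bright at local noon", {
  f <- fixture_field()
  tr <- simulate_track(c(35, 140), as.Date("2021-06-10"), 3, "resident",
                       seed = 9)
  sim <- simulate_sensor_series(tr, f, seed = 10)
  hour_local <- local_solar_hour(sim$series$timestamp_utc,
                                 rep(140, nrow(sim$series)))
  night <- abs(hour_local - 0) < 0.5 | abs(hour_local - 24) < 0.5
  noon <- abs(hour_local - 12) < 0.5
  expect_lt(max(sim$series$light[night]), 0.1)
  expect_gt(min(sim$series$light[noon]), 0.3)
})

test_that("sensor simulation errors when the path leaves the field", {
  f <- simulate_sst_field(dates = as.Date("2021-06-01") + 0:5,
                          lat_range = c(30, 40), lon_range = c(138, 144))
  tr <- tibble::tibble(date = as.Date("2021-06-01") + 0:2,
                       lat = c(35, 36, 45), lon = 140,
                       behavior = "resident")
  expect_error(simulate_sensor_series(tr, f), "extent")
})

test_that("generators are deterministic given the seed", {
  f <- fixture_field()
  tr1 <- simulate_track(c(36, 141), as.Date("2021-06-01"), 20, "resident",
                        seed = 11)
  tr2 <- simulate_track(c(36, 141), as.Date("2021-06-01"), 20, "resident",
                        seed = 11)
  expect_identical(tr1, tr2)
  s1 <- simulate_sensor_series(tr1, f, seed = 12)
  s2 <- simulate_sensor_series(tr2, f, seed = 12)
  expect_identical(s1$series, s2$series)
  p1 <- simulate_pdt_cohort(50, 1980:1984, seed = 13)
  p2 <- simulate_pdt_cohort(50, 1980:1984, seed = 13)
  expect_identical(p1, p2)
})

test_that("PDT cohort respects its spawning-potential probability", {
  p0 <- simulate_pdt_cohort(100, 2020:2021, p_spawning_potential = 0,
                            recapture_rate = 1, seed = 14)
  expect_equal(sum(p0$recapture_lat < 25, na.rm = TRUE), 0)
  p1 <- simulate_pdt_cohort(100, 2020:2021, p_spawning_potential = 1,
                            recapture_rate = 1, seed = 15)
  expect_true(all(p1$recapture_lat < 25))
  pb <- simulate_pdt_cohort(1000, 2020, p_spawning_potential = 0.22,
                            recapture_rate = 1, seed = 16)
  expect_equal(mean(pb$recapture_lat < 25), 0.22, tolerance = 0.04 / 0.22)
  expect_error(simulate_pdt_cohort(10, integer()), "empty")
})
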