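# Shared fixtures; everything is generated in code at test time.

# Small SST field around the study region, one calendar year.
fixture_field <- function(year = 2021, noise_sd_C = 0.1, ...) {
  simulate_sst_field(
    dates = seq(as.Date(sprintf("%d-01-01", year)),
                as.Date(sprintf("%d-12-31", year)), by = "day"),
    noise_sd_C = noise_sd_C,
    seed = 99,
    ...
  )
}

# Constant-condition tag series: fixed position and temperatures, a clean
# solar light curve; handy for aggregation and twilight tests.
fixture_flat_series <- function(n_days = 2, lat = 35, lon = 140,
                                start = as.POSIXct("2021-06-18", tz = "UTC"),
                                temp = 20, depth = 3, sampling_s = 30) {
  n <- n_days * 86400 / sampling_s
  ts <- start + (seq_len(n) - 1) * sampling_s
  elev <- solar_elevation_deg(ts, lat, lon)
  tibble::tibble(
    timestamp_utc = ts,
    depth_m = depth,
    temp_internal_c = temp,
    temp_external_c = temp,
    light = stats::plogis((elev + 6) / 3)
  )
}

# Gonad samples matching the published staging criteria rows.
fixture_gonad_samples <- function() {
  tibble::tibble(
    sample_id = sprintf("g%02d", 1:5),
    fl_cm = c(50, 52, 55, 56, 58),
    gw_g = c(11.75, 12, 30, 52, 52.3),
    bw_g = c(2800, 2900, 3500, 4000, 4200),
    mago = c("Pn", "Ca", "Ty", "Py", "Sy"),
    pof_present = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    ia_pct = c(NA, NA, 20, 60, 20)
  )
}
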