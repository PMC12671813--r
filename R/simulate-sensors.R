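#' Default extraordinary-event shape parameters
#'
#' Body-temperature excursions ramp from baseline to the 31 C event
#' threshold over `ramp_minutes`, rise to `peak_C` over `rise_minutes`,
#' hold for `plateau_minutes`, then decay exponentially
#' (`decay_tau_min`). Successive onsets are separated by 1-3 days and
#' onset local solar hours are afternoon-biased (mode 16:00).
#'
#' @return Parameter list.
#' @export
default_event_params <- function() {
  list(
    ramp_minutes = 35,
    rise_minutes = 5,
    plateau_minutes = 15,
    decay_tau_min = 15,
    peak_C = 32,
    threshold_C = 31,
    interval_days_range = c(1, 3),
    onset_hour_mean = 16,
    onset_hour_sd = 1.5,
    n_events = Inf
  )
}

#' Default light-sensor model parameters
#'
#' Light is a logistic function of solar elevation with inflection at
#' civil twilight (-6 degrees), attenuated exponentially with depth, with
#' multiplicative log-normal sensor noise.
#'
#' @return Parameter list.
#' @export
default_light_params <- function() {
  list(elev0_deg = -6, width_deg = 3, k_per_m = 0.02, noise_frac = 0.05)
}

#' Default depth-behavior parameters
#'
#' Shallow at night, somewhat deeper by day; `post_event_dive_m = 0`
#' disables the optional behavioral-cooling dive after thermal events.
#'
#' @return Parameter list.
#' @export
default_depth_params <- function() {
  list(day_mean_m = 12, night_mean_m = 3, sd_m = 3, post_event_dive_m = 0)
}

#' Simulate an archival-tag sensor series along a true path
#'
#' Emulates a tag sampling depth, internal (peritoneal) temperature,
#' external (ambient) temperature and light at fixed intervals. External
#' temperature is the SST field at the (interpolated) true position minus
#' a small depth-dependent cooling plus sensor noise; internal temperature
#' rides a thermal excess above ambient (damped toward a cap in warm
#' water, emulating thermoregulation) plus optional implanted
#' extraordinary events; light follows solar elevation.
#'
#' @param true_path Tibble from [simulate_track()].
#' @param sst_field An `sst_field` covering the path dates and extent.
#' @param thermal_excess_C Baseline body-minus-ambient excess (default 3).
#' @param event_params `NULL` for no events, or a list as from
#'   [default_event_params()] (partial lists override defaults).
#' @param light_params,depth_params Partial override lists; see
#'   [default_light_params()], [default_depth_params()].
#' @param sampling_s Sampling interval in seconds; must divide 86400.
#' @param noise_sd_C Temperature sensor noise sd (default 0.1).
#' @param cooling_C_per_m Ambient cooling per metre of depth (default 0.05).
#' @param excess_cap_C Internal baseline is damped so it does not exceed
#'   this value in warm water (default 30.5, just under the 31 C event
#'   threshold); `Inf` disables damping.
#' @param seed Integer seed.
#' @return List with `series` (tibble: `timestamp_utc`, `depth_m`,
#'   `temp_internal_c`, `temp_external_c`, `light`), `events` (ground-truth
#'   tibble: `onset_utc`, `crossing_utc`, `peak_utc`, `end_utc`,
#'   `onset_local_solar_hour`) and `true_path`.
#' @export
simulate_sensor_series <- function(true_path, sst_field,
                                   thermal_excess_C = 3,
                                   event_params = NULL,
                                   light_params = list(),
                                   depth_params = list(),
                                   sampling_s = 30,
                                   noise_sd_C = 0.1,
                                   cooling_C_per_m = 0.05,
                                   excess_cap_C = 30.5,
                                   seed = 1L) {
  stopifnot(86400 %% sampling_s == 0)
  lp <- utils::modifyList(default_light_params(), light_params)
  dp <- utils::modifyList(default_depth_params(), depth_params)

  day0 <- as.POSIXct(paste(true_path$date[1], "00:00:00"), tz = "UTC")
  n_days <- nrow(true_path) - 1
  n <- n_days * 86400 / sampling_s
  t_sec <- (seq_len(n) - 1) * sampling_s
  ts <- day0 + t_sec

  # interpolate position between daily (midnight) fixes; unwrap longitude
  day_frac <- t_sec / 86400
  lon_unwrapped <- true_path$lon[1] +
    cumsum(c(0, lon_diff(true_path$lon[-1], true_path$lon[-nrow(true_path)])))
  lat <- stats::approx(0:n_days, true_path$lat, xout = day_frac)$y
  lon <- wrap_lon(stats::approx(0:n_days, lon_unwrapped, xout = day_frac)$y)

  dates <- as.Date(true_path$date[1]) + floor(day_frac)
  if (min(lat) < min(sst_field$lat) || max(lat) > max(sst_field$lat) ||
      min(lon) < min(sst_field$lon) || max(lon) > max(sst_field$lon) ||
      min(dates) < min(sst_field$dates) || max(dates) > max(sst_field$dates)) {
    bad <- which(lat < min(sst_field$lat) | lat > max(sst_field$lat) |
                   lon < min(sst_field$lon) | lon > max(sst_field$lon))
    bad_date <- if (length(bad)) dates[bad[1]] else dates[1]
    stop("simulate_sensor_series: path outside SST field extent on ",
         bad_date)
  }

  elev <- solar_elevation_fast(ts, lat, lon, dates)

  out <- withr_seed(seed, {
    daylight <- stats::plogis(elev / 6)
    depth <- pmax(0, dp$night_mean_m +
                    (dp$day_mean_m - dp$night_mean_m) * daylight +
                    stats::rnorm(n, 0, dp$sd_m))

    sst <- sst_lookup(sst_field, dates, lat, lon)
    external <- sst - cooling_C_per_m * depth + stats::rnorm(n, 0, noise_sd_C)

    excess <- pmin(thermal_excess_C,
                   pmax(0.5, excess_cap_C - (sst - cooling_C_per_m * depth)))
    if (thermal_excess_C == 0) excess <- 0
    internal <- sst - cooling_C_per_m * depth + excess +
      stats::rnorm(n, 0, noise_sd_C)

    events <- empty_event_truth()
    if (!is.null(event_params)) {
      ep <- utils::modifyList(default_event_params(), event_params)
      events <- implant_events(internal, ts, lon, ep, day0, n_days,
                               sampling_s)
      internal <- events$internal
      events <- events$truth
    }

    light_clean <- stats::plogis((elev - lp$elev0_deg) / lp$width_deg) *
      exp(-lp$k_per_m * depth)
    light <- light_clean * exp(stats::rnorm(n, 0, lp$noise_frac))

    list(depth = depth, external = external, internal = internal,
         light = light, events = events)
  })

  series <- tibble::tibble(
    timestamp_utc = ts,
    depth_m = out$depth,
    temp_internal_c = out$internal,
    temp_external_c = out$external,
    light = out$light
  )
  list(series = series, events = out$events, true_path = true_path)
}

# Solar elevation with per-unique-date geometry (fast for long series).
solar_elevation_fast <- function(ts, lat, lon, dates) {
  ud <- unique(dates)
  geom <- solar_geometry(ud)
  i <- match(dates, ud)
  decl <- geom$declination_deg[i] * pi / 180
  eot <- geom$equation_of_time_min[i]
  solar_hour <- frac_hour_utc(ts) + lon / 15 + eot / 60
  h <- (solar_hour - 12) * 15 * pi / 180
  phi <- lat * pi / 180
  sin_elev <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(h)
  asin(pmin(1, pmax(-1, sin_elev))) * 180 / pi
}

# Superimpose extraordinary-event temperature profiles on the internal
# series; returns modified series and the ground-truth event table.
implant_events <- function(internal, ts, lon, ep, day0, n_days, sampling_s) {
  onsets <- c()
  t_day <- stats::runif(1, ep$interval_days_range[1], ep$interval_days_range[2])
  while (t_day < n_days && length(onsets) < ep$n_events) {
    hour_local <- stats::rnorm(1, ep$onset_hour_mean, ep$onset_hour_sd) %% 24
    day_date <- as.Date(day0) + floor(t_day)
    # convert afternoon local solar hour to UTC using that day's longitude
    i_mid <- min(length(lon), (floor(t_day) * 86400 + 43200) / sampling_s + 1)
    hour_utc <- (hour_local - lon[i_mid] / 15) %% 24
    onset <- as.POSIXct(paste(day_date, "00:00:00"), tz = "UTC") +
      round(hour_utc * 3600 / sampling_s) * sampling_s
    onsets <- c(onsets, onset)
    t_day <- t_day + stats::runif(1, ep$interval_days_range[1],
                                  ep$interval_days_range[2])
  }
  if (length(onsets) == 0) {
    return(list(internal = internal,
                truth = empty_event_truth()))
  }
  onsets <- as.POSIXct(onsets, origin = "1970-01-01", tz = "UTC")
  step_min <- sampling_s / 60
  truth <- list()
  for (k in seq_along(onsets)) {
    i0 <- as.numeric(onsets[k] - ts[1], units = "secs") / sampling_s + 1
    if (i0 < 1 || i0 > length(internal)) next
    i0 <- round(i0)
    b0 <- internal[i0]
    total_min <- ep$ramp_minutes + ep$rise_minutes + ep$plateau_minutes + 120
    idx <- i0:min(length(internal), i0 + ceiling(total_min / step_min))
    tmin <- (idx - i0) * step_min
    thr <- ep$threshold_C
    prof <- ifelse(
      tmin <= ep$ramp_minutes,
      b0 + (thr - b0) * tmin / ep$ramp_minutes,
      ifelse(
        tmin <= ep$ramp_minutes + ep$rise_minutes,
        thr + (ep$peak_C - thr) * (tmin - ep$ramp_minutes) / ep$rise_minutes,
        ifelse(
          tmin <= ep$ramp_minutes + ep$rise_minutes + ep$plateau_minutes,
          ep$peak_C,
          internal[idx] + (ep$peak_C - internal[idx]) *
            exp(-(tmin - ep$ramp_minutes - ep$rise_minutes -
                    ep$plateau_minutes) / ep$decay_tau_min)
        )
      )
    )
    internal[idx] <- pmax(internal[idx], prof)
    plateau_end <- onsets[k] +
      (ep$ramp_minutes + ep$rise_minutes + ep$plateau_minutes) * 60
    truth[[length(truth) + 1]] <- tibble::tibble(
      onset_utc = onsets[k],
      crossing_utc = onsets[k] + ep$ramp_minutes * 60,
      peak_utc = onsets[k] + (ep$ramp_minutes + ep$rise_minutes) * 60,
      end_utc = plateau_end,
      onset_local_solar_hour = local_solar_hour(onsets[k], lon[i0])
    )
  }
  if (length(truth) == 0) {
    return(list(internal = internal, truth = empty_event_truth()))
  }
  list(internal = internal, truth = dplyr::bind_rows(truth))
}

empty_event_truth <- function() {
  tibble::tibble(
    onset_utc = as.POSIXct(character(), tz = "UTC"),
    crossing_utc = as.POSIXct(character(), tz = "UTC"),
    peak_utc = as.POSIXct(character(), tz = "UTC"),
    end_utc = as.POSIXct(character(), tz = "UTC"),
    onset_local_solar_hour = numeric()
  )
}
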