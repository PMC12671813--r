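#' Template-fit light geolocation for one day
#'
#' Longitude from the time of local noon (midpoint of dawn and dusk,
#' corrected by the equation of time); latitude from day length via the
#' sunrise equation. Near the equinoxes day length barely varies with
#' latitude, so the latitude estimate is flagged invalid
#' (`lat_valid = FALSE`) when the solar declination is within
#' `decl_min_deg` of zero, and its observation sd is inflated.
#'
#' @param dawn_utc,dusk_utc POSIXct twilight times (dawn < dusk).
#' @param date Date of the estimate (defaults to the dawn date).
#' @param sun_alt_deg Solar altitude the light threshold corresponds to
#'   (0 = geometric sunrise; negative for twilight-level thresholds).
#' @param decl_min_deg Half-width of the equinox exclusion window in
#'   declination degrees (default 3, about 8 days either side).
#' @param obs_sd_lon,obs_sd_lat,obs_sd_lat_equinox Observation sds
#'   (degrees) attached to the estimate for downstream filtering.
#' @return One-row tibble (`RawGeoEstimate`): `date`, `dawn_utc`,
#'   `dusk_utc`, `noon_utc`, `lon_light`, `lat_light`, `lat_valid`,
#'   `obs_sd_lon`, `obs_sd_lat`.
#' @export
template_fit_position <- function(dawn_utc, dusk_utc,
                                  date = as.Date(dawn_utc, tz = "UTC"),
                                  sun_alt_deg = 0,
                                  decl_min_deg = 3,
                                  obs_sd_lon = 0.5,
                                  obs_sd_lat = 1.0,
                                  obs_sd_lat_equinox = 20) {
  if (!(dawn_utc < dusk_utc)) stop("template_fit_position: dawn must precede dusk")
  geom <- solar_geometry(date)
  decl <- geom$declination_deg
  eot_h <- geom$equation_of_time_min / 60

  noon <- dawn_utc + as.numeric(dusk_utc - dawn_utc, units = "secs") / 2
  lon <- wrap_lon(15 * (12 - frac_hour_utc(noon) - eot_h))

  day_h <- as.numeric(dusk_utc - dawn_utc, units = "hours")
  h0 <- day_h * 15 / 2 * pi / 180 # half day arc, radians
  lat <- NA_real_
  lat_valid <- abs(decl) >= decl_min_deg
  if (lat_valid) {
    if (sun_alt_deg == 0) {
      # cos H0 = -tan(lat) tan(decl)
      lat <- atan(-cos(h0) / tan(decl * pi / 180)) * 180 / pi
    } else {
      f <- function(phi) {
        cos(h0) - (sin(sun_alt_deg * pi / 180) -
                     sin(phi) * sin(decl * pi / 180)) /
          (cos(phi) * cos(decl * pi / 180))
      }
      lo <- -66 * pi / 180
      hi <- 66 * pi / 180
      if (is.finite(f(lo)) && is.finite(f(hi)) && f(lo) * f(hi) < 0) {
        lat <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root * 180 / pi
      } else {
        lat_valid <- FALSE
      }
    }
  }
  if (!lat_valid || !is.finite(lat)) {
    lat_valid <- FALSE
    lat <- NA_real_
  }
  tibble::tibble(
    date = as.Date(date),
    dawn_utc = dawn_utc,
    dusk_utc = dusk_utc,
    noon_utc = noon,
    lon_light = lon,
    lat_light = lat,
    lat_valid = lat_valid,
    obs_sd_lon = obs_sd_lon,
    obs_sd_lat = ifelse(lat_valid, obs_sd_lat, obs_sd_lat_equinox)
  )
}

#' Solar altitude corresponding to a light threshold
#'
#' Inverts the logistic light model at a reference depth, giving the
#' solar altitude at which the (noise-free) sensor output crosses the
#' threshold — the `sun_alt_deg` the template fit should use so that
#' detected twilights and the day-length model agree.
#'
#' @param light_threshold Threshold on the raw light scale (0-1).
#' @param light_params List as from [default_light_params()].
#' @param ref_depth_m Typical depth near twilight (default 5 m).
#' @return Solar altitude in degrees (negative below the horizon).
#' @export
light_threshold_alt <- function(light_threshold,
                                light_params = default_light_params(),
                                ref_depth_m = 5) {
  lp <- utils::modifyList(default_light_params(), light_params)
  raw <- light_threshold * exp(lp$k_per_m * ref_depth_m)
  stopifnot(raw > 0, raw < 1)
  lp$elev0_deg + lp$width_deg * stats::qlogis(raw)
}

#' Raw light-based position estimates for a whole series
#'
#' Convenience wrapper: [detect_twilights()] then
#' [template_fit_position()] per day.
#'
#' @inheritParams detect_twilights
#' @param ... Passed to [template_fit_position()].
#' @return Tibble of raw estimates, one row per usable day.
#' @export
light_geolocate <- function(tag_series, light_threshold,
                            smooth_window_min = 10, ...) {
  tw <- detect_twilights(tag_series, light_threshold, smooth_window_min)
  if (nrow(tw) == 0) return(tw)
  dplyr::bind_rows(lapply(seq_len(nrow(tw)), function(i) {
    template_fit_position(tw$dawn_utc[i], tw$dusk_utc[i], tw$date[i], ...)
  }))
}

#' Synthesize raw geolocation estimates directly from a true path
#'
#' Test/benchmark plumbing: adds Gaussian noise at the template-fit error
#' scale to the true daily positions, flagging equinox-window days
#' invalid, so the state-space smoother can be exercised independently of
#' the light model.
#'
#' @param true_path Tibble from [simulate_track()].
#' @param obs_sd_lon,obs_sd_lat,obs_sd_lat_equinox Noise sds (degrees).
#' @param decl_min_deg Equinox window half-width (declination degrees).
#' @param seed Integer seed.
#' @return Tibble of raw estimates (same schema as [light_geolocate()],
#'   without twilight columns).
#' @export
simulate_raw_estimates <- function(true_path,
                                   obs_sd_lon = 0.5, obs_sd_lat = 1.0,
                                   obs_sd_lat_equinox = 20,
                                   decl_min_deg = 3,
                                   seed = 1L) {
  decl <- solar_geometry(true_path$date)$declination_deg
  valid <- abs(decl) >= decl_min_deg
  withr_seed(seed, {
    lat_err <- stats::rnorm(nrow(true_path), 0,
                            ifelse(valid, obs_sd_lat, obs_sd_lat_equinox))
    lon_err <- stats::rnorm(nrow(true_path), 0, obs_sd_lon)
    tibble::tibble(
      date = true_path$date,
      lon_light = wrap_lon(true_path$lon + lon_err),
      lat_light = true_path$lat + lat_err,
      lat_valid = valid,
      obs_sd_lon = obs_sd_lon,
      obs_sd_lat = ifelse(valid, obs_sd_lat, obs_sd_lat_equinox)
    )
  })
}
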