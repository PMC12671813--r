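#' Solar declination and equation of time
#'
#' Spencer-style Fourier approximations, adequate to ~0.1 degree in
#' declination and ~0.5 min in the equation of time — well inside the
#' precision of light-based geolocation.
#'
#' @param date A `Date` (or coercible) vector.
#' @return A tibble with columns `date`, `declination_deg` (within about
#'   +/- 23.46) and `equation_of_time_min` (apparent minus mean solar
#'   time, minutes, in `[-17, 17]`).
#' @export
#' @examples
#' solar_geometry(as.Date("2021-06-21")) # declination near +23.44
solar_geometry <- function(date) {
  date <- as.Date(date)
  if (anyNA(date)) stop("solar_geometry: invalid date")
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  g <- 2 * pi * (doy - 1) / 365
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  eot <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                     0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  tibble::tibble(
    date = date,
    declination_deg = decl * 180 / pi,
    equation_of_time_min = eot
  )
}

#' Solar elevation angle
#'
#' @param time_utc POSIXct (UTC).
#' @param lat,lon Position in decimal degrees.
#' @return Elevation of the sun above the horizon, degrees (vectorised).
#' @export
solar_elevation_deg <- function(time_utc, lat, lon) {
  geom <- solar_geometry(as.Date(time_utc, tz = "UTC"))
  decl <- geom$declination_deg * pi / 180
  # hour angle: 0 at local solar noon, 15 deg per hour
  solar_hour <- frac_hour_utc(time_utc) + lon / 15 +
    geom$equation_of_time_min / 60
  h <- (solar_hour - 12) * 15 * pi / 180
  phi <- lat * pi / 180
  sin_elev <- sin(phi) * sin(decl) + cos(phi) * cos(decl) * cos(h)
  asin(pmin(1, pmax(-1, sin_elev))) * 180 / pi
}

#' Astronomical day length
#'
#' Closed-form day length from the sunrise equation, for a given solar
#' altitude defining "day" (0 for geometric sunrise/sunset).
#'
#' @param date Date vector.
#' @param lat Latitude, degrees.
#' @param sun_alt_deg Solar altitude defining the day boundary (default 0).
#' @return Day length in hours; 0 or 24 in polar night/day.
#' @export
day_length_hours <- function(date, lat, sun_alt_deg = 0) {
  decl <- solar_geometry(date)$declination_deg * pi / 180
  phi <- lat * pi / 180
  alt <- sun_alt_deg * pi / 180
  cos_h <- (sin(alt) - sin(phi) * sin(decl)) / (cos(phi) * cos(decl))
  h <- acos(pmin(1, pmax(-1, cos_h)))
  2 * h * 180 / pi / 15
}
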