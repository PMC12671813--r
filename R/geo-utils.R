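#' @importFrom rlang .data
NULL

# Spherical earth radius used throughout (km). Sub-0.5% error vs the
# ellipsoid, the usual movement-ecology convention.
EARTH_RADIUS_KM <- 6371.0

#' Great-circle distance between two points
#'
#' Haversine distance on a sphere of radius 6371 km.
#'
#' @param p1,p2 Numeric vectors `c(lat, lon)` in decimal degrees, or
#'   two-column matrices (`lat`, `lon`) of equal length.
#' @return Distance in km (vectorised).
#' @export
#' @examples
#' great_circle_km(c(35, 140), c(36, 140)) # ~111.19 km
great_circle_km <- function(p1, p2) {
  p1 <- to_lonlat_matrix(p1)
  p2 <- to_lonlat_matrix(p2)
  geosphere::distHaversine(p1, p2, r = EARTH_RADIUS_KM)
}

#' Initial great-circle bearing between two points
#'
#' @inheritParams great_circle_km
#' @return Bearing in degrees clockwise from north, in `[0, 360)`.
#' @export
initial_bearing_deg <- function(p1, p2) {
  m1 <- to_lonlat_matrix(p1)
  m2 <- to_lonlat_matrix(p2)
  same <- rowSums(abs(m1 - m2)) < 1e-12
  if (any(same)) {
    stop("initial_bearing_deg: bearing undefined for identical points")
  }
  b <- geosphere::bearing(m1, m2)
  (b + 360) %% 360
}

#' Advance a position along a bearing on the sphere
#'
#' @param p `c(lat, lon)` or matrix of positions (degrees).
#' @param bearing_deg Bearing clockwise from north (degrees).
#' @param distance_km Distance to travel (km).
#' @return Matrix with columns `lat`, `lon`.
#' @export
destination_point <- function(p, bearing_deg, distance_km) {
  m <- to_lonlat_matrix(p)
  d <- geosphere::destPoint(m, bearing_deg, distance_km * 1000,
                            r = EARTH_RADIUS_KM * 1000)
  cbind(lat = d[, 2], lon = wrap_lon(d[, 1]))
}

# Accept c(lat, lon) or an n x 2 (lat, lon) matrix; return geosphere's
# (lon, lat) column order.
to_lonlat_matrix <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2)
    p <- matrix(p, ncol = 2)
  }
  if (any(abs(p[, 1]) > 90)) {
    stop("latitude outside [-90, 90]; expected (lat, lon) order")
  }
  cbind(p[, 2], p[, 1])
}

#' Wrap longitudes into (-180, 180]
#' @param lon Longitudes in degrees.
#' @return Wrapped longitudes.
#' @export
wrap_lon <- function(lon) {
  w <- ((lon + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

# Difference lon1 - lon2 mapped to (-180, 180]; safe across the dateline.
lon_diff <- function(lon1, lon2) wrap_lon(lon1 - lon2)

# Fractional UTC hour of a POSIXct timestamp.
frac_hour_utc <- function(t) {
  as.numeric(t - trunc(t, "days"), units = "hours")
}

#' Local solar hour at a longitude
#'
#' Local solar time is UTC + lon/15 hours; no civil time zones are used.
#'
#' @param time_utc POSIXct (UTC).
#' @param lon Longitude in degrees east.
#' @return Fractional hour in `[0, 24)`.
#' @export
local_solar_hour <- function(time_utc, lon) {
  (frac_hour_utc(time_utc) + lon / 15) %% 24
}
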