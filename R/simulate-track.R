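#' Default daily step parameters for the two movement modes
#'
#' Residents take short steps (mean 34.6, sd 27.6 km/day) with no
#' directional bias; migrants take long steps (mean 77, sd 61 km/day)
#' concentrated around due south (von Mises bearing, concentration
#' `kappa`). Step lengths are truncated normal on `[0, max_step_km]`.
#'
#' @param behavior `"resident"` or `"migrant"`.
#' @return List with `mean_km`, `sd_km`, `max_step_km`, `bearing_mode_deg`,
#'   `kappa` (0 = uniform bearings).
#' @export
default_step_params <- function(behavior = c("resident", "migrant")) {
  behavior <- match.arg(behavior)
  if (behavior == "resident") {
    list(mean_km = 34.6, sd_km = 27.6, max_step_km = 300,
         bearing_mode_deg = 180, kappa = 0)
  } else {
    list(mean_km = 77, sd_km = 61, max_step_km = 300,
         bearing_mode_deg = 180, kappa = 1)
  }
}

#' Simulate a true daily movement path
#'
#' Positions are advanced on a sphere of radius 6371 km; daily step lengths
#' are truncated normal, bearings uniform (resident) or von Mises around
#' due south (migrant). Latitudes are kept inside `lat_bounds` by
#' resampling the bearing when a step would exit.
#'
#' @param release_position `c(lat, lon)` in decimal degrees.
#' @param release_date Date of release.
#' @param n_days Number of daily steps (path has `n_days + 1` positions).
#' @param behavior `"resident"` or `"migrant"`.
#' @param step_params List as from [default_step_params()]; entries given
#'   override the defaults for `behavior`.
#' @param lat_bounds Permissible latitude range (default `c(-30, 55)`).
#' @param seed Integer seed.
#' @return A tibble (`true_path`): `date`, `lat`, `lon`, `behavior`.
#' @export
simulate_track <- function(release_position, release_date, n_days,
                           behavior = c("resident", "migrant"),
                           step_params = list(),
                           lat_bounds = c(-30, 55),
                           seed = 1L) {
  behavior <- match.arg(behavior)
  stopifnot(n_days >= 1)
  sp <- utils::modifyList(default_step_params(behavior), step_params)
  if (sp$mean_km <= 0) stop("simulate_track: nonpositive step mean")

  lat <- numeric(n_days + 1)
  lon <- numeric(n_days + 1)
  lat[1] <- release_position[1]
  lon[1] <- release_position[2]
  withr_seed(seed, {
    for (d in seq_len(n_days)) {
      step <- rtruncnorm1(sp$mean_km, sp$sd_km, 0, sp$max_step_km)
      for (try in 1:50) {
        b <- if (sp$kappa <= 0) {
          stats::runif(1, 0, 360)
        } else {
          rvonmises1(sp$bearing_mode_deg, sp$kappa)
        }
        nxt <- destination_point(c(lat[d], lon[d]), b, step)
        if (nxt[1] >= lat_bounds[1] && nxt[1] <= lat_bounds[2]) break
      }
      if (nxt[1] < lat_bounds[1] || nxt[1] > lat_bounds[2]) {
        nxt <- c(lat[d], lon[d]) # stay put if no admissible bearing found
      }
      lat[d + 1] <- nxt[1]
      lon[d + 1] <- nxt[2]
    }
  })
  tibble::tibble(
    date = release_date + 0:n_days,
    lat = lat, lon = lon,
    behavior = behavior
  )
}

# One truncated-normal draw on [lo, hi] by rejection (acceptance is high for
# the step distributions used here). sd = 0 returns the clamped mean.
rtruncnorm1 <- function(mean, sd, lo, hi) {
  if (sd <= 0) return(min(max(mean, lo), hi))
  for (i in 1:1000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
  min(max(mean, lo), hi)
}

# One von Mises draw (degrees) by the Best-Fisher rejection algorithm.
rvonmises1 <- function(mu_deg, kappa) {
  if (kappa < 1e-8) return(stats::runif(1, 0, 360))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  repeat {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (c0 * (2 - c0) - u2 > 0 || log(c0 / u2) + 1 - c0 >= 0) {
      u3 <- stats::runif(1)
      theta <- sign(u3 - 0.5) * acos(f)
      return((mu_deg + theta * 180 / pi) %% 360)
    }
  }
}
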