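#' Default configuration for the state-space track smoother
#'
#' @return List: observation sds (`sd_lon`, `sd_lat` in degrees, `sd_sst`
#'   in degrees C), process-noise handling (`sigma_kms` fixed value in
#'   km/sqrt(day), or `NULL` to estimate by maximum likelihood within
#'   `sigma_bounds`), UKF scaling (`ukf_kappa`), divergence guard
#'   (`divergence_nsd`, `divergence_days`) and optional initial state
#'   (`init_latlon`).
#' @export
default_track_config <- function() {
  list(
    sd_lon = 0.5,
    sd_lat = 1.0,
    sd_sst = 0.3,
    sigma_kms = NULL,
    sigma_bounds = c(10, 300),
    ukf_kappa = 1,
    divergence_nsd = 6,
    divergence_days = 3,
    init_latlon = NULL
  )
}

KM_PER_DEG <- EARTH_RADIUS_KM * pi / 180 # 111.195 km per degree latitude

#' Refine light-based positions with SST matching in a state-space smoother
#'
#' Daily positions follow a random walk on the sphere with isotropic
#' process noise `sigma` (km/sqrt(day)). Observations per day are the
#' light-based longitude, the light-based latitude (sd inflated on
#' equinox-window days), and the tag-measured SST compared with the
#' gridded field at the state position. The SST observation is nonlinear
#' in the state and is handled by the unscented transform; a forward
#' unscented Kalman filter is followed by a Rauch-Tung-Striebel smoother.
#' When `sigma` is not fixed it is estimated by maximising the filter
#' log-likelihood with a bounded 1-D search.
#'
#' @param raw_estimates Tibble from [light_geolocate()] or
#'   [simulate_raw_estimates()]: `date`, `lon_light`, `lat_light`,
#'   `lat_valid`, `obs_sd_lon`, `obs_sd_lat`.
#' @param daily_sst Tibble from [tag_sst_daily()] (`date`, `sst_c`), or
#'   `NULL` to smooth on light alone.
#' @param sst_field An `sst_field`, or `NULL` when `daily_sst` is `NULL`.
#' @param config List as from [default_track_config()]; partial lists
#'   override defaults.
#' @return A `Track` tibble: `date`, `lat`, `lon`, `sd_lat`, `sd_lon`,
#'   plus per-day filter sds (`sd_lat_filter`, `sd_lon_filter`) and
#'   attributes `log_lik` and `sigma_kms`.
#' @export
refine_track <- function(raw_estimates, daily_sst = NULL, sst_field = NULL,
                         config = list()) {
  cfg <- utils::modifyList(default_track_config(), config)
  obs <- build_observations(raw_estimates, daily_sst, cfg)
  if (nrow(obs) < 3) stop("refine_track: need >= 3 days with observations")
  if (!any(obs$has_lon | obs$has_lat | obs$has_sst)) {
    stop("refine_track: no valid observations")
  }

  if (is.null(cfg$sigma_kms)) {
    nll <- function(sig) -ukf_pass(obs, sst_field, cfg, sig,
                                   smooth = FALSE)$log_lik
    opt <- stats::optimize(nll, cfg$sigma_bounds, tol = 2)
    sigma <- opt$minimum
  } else {
    sigma <- cfg$sigma_kms
  }
  fit <- ukf_pass(obs, sst_field, cfg, sigma, smooth = TRUE)
  out <- tibble::tibble(
    date = obs$date,
    lat = fit$xs[, 1],
    lon = wrap_lon(fit$xs[, 2]),
    sd_lat = sqrt(fit$Ps[, 1]),
    sd_lon = sqrt(fit$Ps[, 2]),
    sd_lat_filter = sqrt(fit$Pf_diag[, 1]),
    sd_lon_filter = sqrt(fit$Pf_diag[, 2])
  )
  attr(out, "log_lik") <- fit$log_lik
  attr(out, "sigma_kms") <- sigma
  attr(out, "n_reinit") <- fit$n_reinit
  out
}

# Assemble a per-day observation table over the full date span.
build_observations <- function(raw_estimates, daily_sst, cfg) {
  dates <- seq(min(raw_estimates$date), max(raw_estimates$date), by = "day")
  obs <- tibble::tibble(date = dates) |>
    dplyr::left_join(raw_estimates, by = "date")
  obs$has_lon <- !is.na(obs$lon_light)
  obs$has_lat <- !is.na(obs$lat_light)
  obs$sd_lat_use <- ifelse(obs$has_lat, obs$obs_sd_lat, NA_real_)
  obs$sd_lon_use <- ifelse(obs$has_lon,
                           ifelse(is.na(obs$obs_sd_lon), cfg$sd_lon,
                                  obs$obs_sd_lon), NA_real_)
  if (!is.null(daily_sst)) {
    obs <- dplyr::left_join(
      obs, dplyr::select(daily_sst, "date", "sst_c"), by = "date"
    )
  } else {
    obs$sst_c <- NA_real_
  }
  obs$has_sst <- !is.na(obs$sst_c)
  obs
}

# One forward filter pass (with optional RTS smoothing). State x = (lat,
# unwrapped lon) in degrees. Returns log-likelihood and state estimates.
ukf_pass <- function(obs, sst_field, cfg, sigma_kms, smooth = TRUE) {
  n <- nrow(obs)
  # initial state: first day with both coordinates observed (or config)
  if (!is.null(cfg$init_latlon)) {
    x <- c(cfg$init_latlon[1], cfg$init_latlon[2])
  } else {
    i_lat <- which(obs$has_lat & obs$lat_valid)[1]
    if (is.na(i_lat)) i_lat <- which(obs$has_lat)[1]
    i_lon <- which(obs$has_lon)[1]
    x <- c(if (!is.na(i_lat)) obs$lat_light[i_lat] else 30,
           if (!is.na(i_lon)) obs$lon_light[i_lon] else mean(sst_field$lon))
  }
  lon_ref <- x[2] # unwrap observations near the running reference
  P <- diag(c(4, 4))

  xf <- matrix(NA_real_, n, 2)
  Pf <- array(NA_real_, c(n, 2, 2))
  xp <- matrix(NA_real_, n, 2)
  Pp <- array(NA_real_, c(n, 2, 2))
  log_lik <- 0
  n_bad <- 0
  n_reinit <- 0

  for (t in seq_len(n)) {
    sig_lat <- sigma_kms / KM_PER_DEG
    sig_lon <- sigma_kms / (KM_PER_DEG * cos(pmin(85, abs(x[1])) * pi / 180))
    Q <- diag(c(sig_lat^2, sig_lon^2))
    if (t > 1) P <- P + Q
    xp[t, ] <- x
    Pp[t, , ] <- P

    z <- c(); hsel <- c(); rdiag <- c()
    if (obs$has_lat[t]) {
      z <- c(z, obs$lat_light[t]); hsel <- c(hsel, "lat")
      rdiag <- c(rdiag, obs$sd_lat_use[t]^2)
    }
    if (obs$has_lon[t]) {
      z <- c(z, x[2] + lon_diff(obs$lon_light[t], x[2]))
      hsel <- c(hsel, "lon")
      rdiag <- c(rdiag, obs$sd_lon_use[t]^2)
    }
    if (obs$has_sst[t]) {
      z <- c(z, obs$sst_c[t]); hsel <- c(hsel, "sst")
      rdiag <- c(rdiag, cfg$sd_sst^2)
    }
    if (length(z) > 0) {
      up <- ukf_update(x, P, z, hsel, rdiag, obs$date[t], sst_field,
                       cfg$ukf_kappa)
      # divergence guard: repeated wild innovations trigger reinitialization
      if (up$max_nsd > cfg$divergence_nsd) {
        n_bad <- n_bad + 1
        if (n_bad > cfg$divergence_days) {
          warning("refine_track: filter divergence; re-initializing")
          n_reinit <- n_reinit + 1
          P <- diag(c(25, 25))
          up <- ukf_update(x, P, z, hsel, rdiag, obs$date[t], sst_field,
                           cfg$ukf_kappa)
          n_bad <- 0
        }
      } else {
        n_bad <- 0
      }
      x <- up$x
      P <- up$P
      log_lik <- log_lik + up$ll
    }
    xf[t, ] <- x
    Pf[t, , ] <- P
  }

  out <- list(log_lik = log_lik, n_reinit = n_reinit,
              Pf_diag = cbind(Pf[, 1, 1], Pf[, 2, 2]))
  if (!smooth) return(out)

  xs <- xf
  Ps <- Pf
  for (t in (n - 1):1) {
    G <- Pf[t, , ] %*% solve(Pp[t + 1, , ] +
                               diag(1e-10, 2))
    xs[t, ] <- xf[t, ] + as.vector(G %*% (xs[t + 1, ] - xp[t + 1, ]))
    Ps[t, , ] <- Pf[t, , ] + G %*% (Ps[t + 1, , ] - Pp[t + 1, , ]) %*% t(G)
  }
  out$xs <- xs
  out$Ps <- cbind(pmax(Ps[, 1, 1], 0), pmax(Ps[, 2, 2], 0))
  out
}

# Unscented measurement update for state (lat, lon).
ukf_update <- function(x, P, z, hsel, rdiag, date, sst_field, kappa) {
  nx <- 2
  lam <- kappa
  S <- tryCatch(chol((nx + lam) * P), error = function(e) {
    chol((nx + lam) * (P + diag(1e-8, 2)))
  })
  pts <- matrix(0, 2 * nx + 1, nx)
  pts[1, ] <- x
  Sm <- t(S)
  for (i in 1:nx) {
    pts[1 + i, ] <- x + Sm[, i]
    pts[1 + nx + i, ] <- x - Sm[, i]
  }
  wm <- c(lam / (nx + lam), rep(1 / (2 * (nx + lam)), 2 * nx))

  nz <- length(z)
  Z <- matrix(0, nrow(pts), nz)
  for (j in seq_len(nz)) {
    Z[, j] <- switch(hsel[j],
      lat = pts[, 1],
      lon = pts[, 2],
      sst = sst_lookup(sst_field, rep(date, nrow(pts)), pts[, 1],
                       wrap_lon(pts[, 2]))
    )
  }
  if (anyNA(Z)) {
    # state sigma points off the SST grid: drop the SST component
    keep <- !apply(Z, 2, anyNA)
    if (!any(keep)) return(list(x = x, P = P, ll = 0, max_nsd = 0))
    Z <- Z[, keep, drop = FALSE]
    z <- z[keep]
    rdiag <- rdiag[keep]
    nz <- length(z)
  }
  zbar <- colSums(wm * Z)
  dZ <- sweep(Z, 2, zbar)
  Szz <- t(dZ) %*% (wm * dZ) + diag(rdiag, nz)
  dX <- sweep(pts, 2, x)
  Sxz <- t(dX) %*% (wm * dZ)
  K <- Sxz %*% solve(Szz)
  innov <- z - zbar
  xnew <- as.vector(x + K %*% innov)
  Pnew <- P - K %*% Szz %*% t(K)
  Pnew <- (Pnew + t(Pnew)) / 2
  ll <- -0.5 * (nz * log(2 * pi) + determinant(Szz)$modulus[1] +
                  sum(innov * solve(Szz, innov)))
  max_nsd <- max(abs(innov) / sqrt(diag(Szz)))
  list(x = xnew, P = Pnew, ll = ll, max_nsd = max_nsd)
}
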