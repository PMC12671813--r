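#' Discrete grid-filter track estimate (validation oracle)
#'
#' Brute-force hidden-Markov smoother over a regular lat/lon grid with
#' the same observation likelihoods as [refine_track()] and a discretized
#' Gaussian random-walk kernel (separable in latitude and longitude).
#' Used to validate the unscented smoother; slower but assumption-free
#' about linearity.
#'
#' @inheritParams refine_track
#' @param grid_resolution_deg Grid cell size in degrees (default 1).
#' @param lat_range,lon_range Grid extent; defaults to the raw-estimate
#'   bounding box padded by 5 degrees.
#' @param sigma_kms Process noise, km/sqrt(day) (no estimation here).
#' @return Track tibble: `date`, `lat`, `lon`, `sd_lat`, `sd_lon`
#'   (posterior mean and sd per day).
#' @export
grid_filter_oracle <- function(raw_estimates, daily_sst = NULL,
                               sst_field = NULL,
                               grid_resolution_deg = 1,
                               lat_range = NULL, lon_range = NULL,
                               sigma_kms = 100,
                               config = list()) {
  cfg <- utils::modifyList(default_track_config(), config)
  obs <- build_observations(raw_estimates, daily_sst, cfg)
  if (is.null(lat_range)) {
    lat_range <- range(obs$lat_light, na.rm = TRUE) + c(-5, 5)
  }
  if (is.null(lon_range)) {
    lon_range <- range(obs$lon_light, na.rm = TRUE) + c(-5, 5)
  }
  lat <- seq(lat_range[1], lat_range[2], by = grid_resolution_deg)
  lon <- seq(lon_range[1], lon_range[2], by = grid_resolution_deg)
  nlat <- length(lat)
  nlon <- length(lon)
  n <- nrow(obs)

  # per-day emission log-likelihood matrices [nlat, nlon]
  emis <- vector("list", n)
  if (!is.null(sst_field)) {
    grid_pts <- expand.grid(lat = lat, lon = lon, KEEP.OUT.ATTRS = FALSE)
  }
  for (t in seq_len(n)) {
    ll <- matrix(0, nlat, nlon)
    if (obs$has_lat[t]) {
      ll <- ll + matrix(stats::dnorm(lat, obs$lat_light[t],
                                     obs$sd_lat_use[t], log = TRUE),
                        nlat, nlon)
    }
    if (obs$has_lon[t]) {
      dl <- lon_diff(lon, obs$lon_light[t])
      ll <- ll + matrix(stats::dnorm(dl, 0, obs$sd_lon_use[t], log = TRUE),
                        nlat, nlon, byrow = TRUE)
    }
    if (obs$has_sst[t] && !is.null(sst_field)) {
      fsst <- sst_lookup(sst_field, rep(obs$date[t], nrow(grid_pts)),
                         grid_pts$lat, grid_pts$lon)
      lsst <- stats::dnorm(obs$sst_c[t], fsst, cfg$sd_sst, log = TRUE)
      lsst[is.na(lsst)] <- -1e6
      ll <- ll + matrix(lsst, nlat, nlon)
    }
    emis[[t]] <- ll
  }

  # separable transition kernels (degrees of lat/lon per sqrt(day))
  sd_lat_deg <- sigma_kms / KM_PER_DEG
  mid_lat <- mean(lat_range)
  sd_lon_deg <- sigma_kms / (KM_PER_DEG * cos(mid_lat * pi / 180))
  klat <- gauss_kernel(sd_lat_deg / grid_resolution_deg, nlat)
  klon <- gauss_kernel(sd_lon_deg / grid_resolution_deg, nlon)

  blur <- function(m) {
    m <- apply(m, 2, function(col) conv_same(col, klat))
    t(apply(m, 1, function(row) conv_same(row, klon)))
  }
  normalize <- function(m) m / sum(m)

  # forward
  alpha <- vector("list", n)
  a <- normalize(exp(emis[[1]] - max(emis[[1]])))
  alpha[[1]] <- a
  for (t in 2:n) {
    a <- blur(a)
    a <- a * exp(emis[[t]] - max(emis[[t]]))
    alpha[[t]] <- normalize(a)
    a <- alpha[[t]]
  }
  # backward
  beta <- vector("list", n)
  b <- matrix(1 / (nlat * nlon), nlat, nlon)
  beta[[n]] <- b
  for (t in (n - 1):1) {
    m <- beta[[t + 1]] * exp(emis[[t + 1]] - max(emis[[t + 1]]))
    beta[[t]] <- normalize(blur(m))
  }

  res <- lapply(seq_len(n), function(t) {
    post <- normalize(alpha[[t]] * beta[[t]])
    pl <- rowSums(post)
    po <- colSums(post)
    mlat <- sum(pl * lat)
    mlon <- sum(po * lon)
    v_lat <- sqrt(pmax(0, sum(pl * lat^2) - mlat^2))
    v_lon <- sqrt(pmax(0, sum(po * lon^2) - mlon^2))
    tibble::tibble(
      date = obs$date[t],
      lat = mlat,
      lon = wrap_lon(mlon),
      sd_lat = v_lat,
      sd_lon = v_lon
    )
  })
  dplyr::bind_rows(res)
}

gauss_kernel <- function(sd_cells, n_max) {
  half <- min(n_max - 1, max(1L, ceiling(4 * sd_cells)))
  x <- -half:half
  k <- stats::dnorm(x, 0, max(sd_cells, 1e-6))
  k / sum(k)
}

# 'same' convolution with a centered kernel, edge-renormalized so mass
# reflected off the boundary is preserved.
conv_same <- function(x, k) {
  n <- length(x)
  half <- (length(k) - 1) / 2
  full <- stats::convolve(c(rep(0, half), x, rep(0, half)), rev(k),
                          type = "filter")
  # renormalize by the kernel mass actually inside the domain
  mass <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), rev(k),
                          type = "filter")
  full / pmax(mass, 1e-12)
}
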