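#' Simulate a gridded daily sea-surface temperature field
#'
#' Generates a synthetic stand-in for a satellite SST product: a linear
#' meridional gradient (colder northward by default) superposed on a
#' seasonal cycle peaking in late summer, plus smooth random spatial
#' anomalies, clamped to a tropical plateau so low latitudes saturate
#' around `sst_max_C` as real western-Pacific SST does.
#'
#' @param lat_range,lon_range Numeric length-2 extents in decimal degrees.
#' @param dates Vector of `Date`s (ordered calendar days).
#' @param resolution_deg Grid spacing in degrees (default 1).
#' @param base_C Temperature at `lat_ref` when the seasonal term is zero.
#' @param lat_ref Reference latitude for the gradient anchor (default 30).
#' @param lat_gradient_C_per_deg Cooling per degree northward; must be
#'   nonzero (default 0.5).
#' @param seasonal_amp_C Amplitude of the annual cycle (default 4).
#' @param peak_doy Day of year of the seasonal maximum (default 228,
#'   mid-August, as in the NW Pacific).
#' @param noise_sd_C Standard deviation of smooth spatial anomalies
#'   (default 0.1); 0 disables them.
#' @param sst_min_C,sst_max_C Clamp range (default 2 and 30).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return An `sst_field` object: list with `dates`, `lat`, `lon` (strictly
#'   increasing grids) and `sst` (array `[date, lat, lon]`, degrees C).
#' @export
simulate_sst_field <- function(lat_range = c(-32, 55),
                               lon_range = c(120, 175),
                               dates,
                               resolution_deg = 1,
                               base_C = 24.85,
                               lat_ref = 30,
                               lat_gradient_C_per_deg = 0.5,
                               seasonal_amp_C = 4,
                               peak_doy = 228,
                               noise_sd_C = 0.1,
                               sst_min_C = 2,
                               sst_max_C = 30,
                               seed = 1L) {
  dates <- as.Date(dates)
  if (length(dates) == 0) stop("simulate_sst_field: empty date range")
  if (lat_gradient_C_per_deg == 0) {
    stop("simulate_sst_field: meridional gradient must be nonzero")
  }
  if (diff(range(lat_range)) <= 0 || diff(range(lon_range)) <= 0) {
    stop("simulate_sst_field: degenerate spatial extent")
  }
  lat <- seq(lat_range[1], lat_range[2], by = resolution_deg)
  lon <- seq(lon_range[1], lon_range[2], by = resolution_deg)
  doy <- as.integer(strftime(dates, "%j", tz = "UTC"))
  seasonal <- seasonal_amp_C * cos(2 * pi * (doy - peak_doy) / 365)
  lat_term <- -lat_gradient_C_per_deg * (lat - lat_ref)

  sst <- array(0, dim = c(length(dates), length(lat), length(lon)))
  # deterministic structure: date x lat, constant in lon
  for (i in seq_along(dates)) {
    sst[i, , ] <- base_C + seasonal[i] + lat_term
  }
  if (noise_sd_C > 0) {
    withr_seed(seed, {
      # smooth anomalies: a few random-phase harmonics per date
      for (i in seq_along(dates)) {
        ph <- stats::runif(4, 0, 2 * pi)
        a <- outer(
          sin(2 * pi * lat / 17 + ph[1]) + 0.6 * sin(2 * pi * lat / 7 + ph[2]),
          sin(2 * pi * lon / 19 + ph[3]) + 0.6 * sin(2 * pi * lon / 8 + ph[4])
        )
        sst[i, , ] <- sst[i, , ] + noise_sd_C * a / stats::sd(a)
      }
    })
  }
  sst <- pmin(pmax(sst, sst_min_C), sst_max_C) # keeps the array dims
  structure(
    list(dates = dates, lat = lat, lon = lon, sst = sst),
    class = "sst_field"
  )
}

# Evaluate code with a temporary RNG state seeded by `seed`.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Look up SST at positions
#'
#' Bilinear interpolation in space, nearest neighbour in time — the lookup
#' convention assumed by the track smoother.
#'
#' @param field An `sst_field`.
#' @param date Date vector (recycled against positions).
#' @param lat,lon Positions in decimal degrees.
#' @return SST in degrees C (NA outside the grid).
#' @export
sst_lookup <- function(field, date, lat, lon) {
  n <- max(length(date), length(lat), length(lon))
  date <- rep_len(as.Date(date), n)
  lat <- rep_len(lat, n)
  lon <- rep_len(lon, n)

  ti <- findInterval(as.numeric(date) + 0.5, as.numeric(field$dates))
  ti <- pmin(pmax(ti, 1L), length(field$dates))
  # nearest in time
  ti2 <- pmin(ti + 1L, length(field$dates))
  nearer <- abs(as.numeric(field$dates[ti2]) - as.numeric(date)) <
    abs(as.numeric(field$dates[ti]) - as.numeric(date))
  ti[nearer] <- ti2[nearer]

  li <- findInterval(lat, field$lat, rightmost.closed = TRUE)
  oi <- findInterval(lon, field$lon, rightmost.closed = TRUE)
  out <- rep(NA_real_, n)
  ok <- li >= 1 & li < length(field$lat) & oi >= 1 & oi < length(field$lon) &
    !is.na(lat) & !is.na(lon)
  if (!any(ok)) return(out)
  li <- li[ok]; oi <- oi[ok]; tio <- ti[ok]
  wy <- (lat[ok] - field$lat[li]) / (field$lat[li + 1] - field$lat[li])
  wx <- (lon[ok] - field$lon[oi]) / (field$lon[oi + 1] - field$lon[oi])
  idx <- function(dlat, dlon) {
    cbind(tio, li + dlat, oi + dlon)
  }
  v <- (1 - wy) * (1 - wx) * field$sst[idx(0, 0)] +
    wy * (1 - wx) * field$sst[idx(1, 0)] +
    (1 - wy) * wx * field$sst[idx(0, 1)] +
    wy * wx * field$sst[idx(1, 1)]
  out[ok] <- v
  out
}

#' Write / read an SST field as long-format CSV
#'
#' Columns: `date`, `lat`, `lon`, `sst_c`.
#'
#' @param field An `sst_field`.
#' @param path File path.
#' @return `read_sst_csv` returns an `sst_field`.
#' @export
write_sst_csv <- function(field, path) {
  grid <- expand.grid(
    lon = field$lon, lat = field$lat, date = field$dates,
    KEEP.OUT.ATTRS = FALSE
  )
  # array index order is [date, lat, lon]; expand.grid varies lon fastest
  grid$sst_c <- as.vector(aperm(field$sst, c(3, 2, 1)))
  readr::write_csv(grid[, c("date", "lat", "lon", "sst_c")], path)
  invisible(path)
}

#' @rdname write_sst_csv
#' @export
read_sst_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  stopifnot(all(c("date", "lat", "lon", "sst_c") %in% names(df)))
  dates <- sort(unique(as.Date(df$date)))
  lat <- sort(unique(df$lat))
  lon <- sort(unique(df$lon))
  sst <- array(NA_real_, dim = c(length(dates), length(lat), length(lon)))
  ti <- match(as.Date(df$date), dates)
  li <- match(df$lat, lat)
  oi <- match(df$lon, lon)
  sst[cbind(ti, li, oi)] <- df$sst_c
  if (anyNA(sst)) stop("read_sst_csv: incomplete grid")
  structure(
    list(dates = dates, lat = lat, lon = lon, sst = sst),
    class = "sst_field"
  )
}
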