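#' Detect dawn and dusk from a tag light record
#'
#' The log-light curve is smoothed with a centered running median
#' (robust to brief dive-attenuation dropouts) and threshold crossings
#' located: a daylight period runs from an upward crossing (dawn) to the
#' last downward crossing before the next dawn (dusk), so midday dips
#' shorter than the smoothing window do not split the day. Periods with
#' implausible length are dropped with a warning; the date assigned to a
#' period is the UTC date of its midpoint.
#'
#' @param tag_series Tibble with `timestamp_utc` and `light`.
#' @param light_threshold Light level defining day vs night, on the raw
#'   light scale; must lie inside the observed range or all days are
#'   skipped (with warnings).
#' @param smooth_window_min Running-median window (minutes, default 10).
#' @param min_day_h,max_day_h Plausible day-length range (default 3-21 h).
#' @return Tibble: `date`, `dawn_utc`, `dusk_utc` (one row per usable day).
#' @export
detect_twilights <- function(tag_series, light_threshold,
                             smooth_window_min = 10,
                             min_day_h = 3, max_day_h = 21) {
  ts <- tag_series$timestamp_utc
  n <- length(ts)
  if (n < 2) stop("detect_twilights: series too short")
  sampling_s <- as.numeric(stats::median(diff(as.numeric(ts))))
  if ((n - 1) * sampling_s < 86400) {
    stop("detect_twilights: series spans less than one full day")
  }
  w <- max(1L, round(smooth_window_min * 60 / sampling_s))
  if (w %% 2 == 0) w <- w + 1L
  loglight <- log(pmax(tag_series$light, 1e-12))
  sm <- stats::runmed(loglight, w, endrule = "keep")

  above <- sm > log(light_threshold)
  n_days_total <- length(unique(as.Date(ts, tz = "UTC")))
  if (all(above) || all(!above)) {
    for (i in seq_len(n_days_total)) {
      warning("detect_twilights: no twilight crossing; day skipped")
    }
    return(tibble::tibble(date = as.Date(character()),
                          dawn_utc = as.POSIXct(character(), tz = "UTC"),
                          dusk_utc = as.POSIXct(character(), tz = "UTC")))
  }
  up <- which(diff(above) == 1) + 1L   # first sample above
  down <- which(diff(above) == -1)     # last sample above
  # pair each dawn with the last dusk before the next dawn
  res <- list()
  for (k in seq_along(up)) {
    lim <- if (k < length(up)) up[k + 1] else n + 1L
    cand <- down[down >= up[k] & down < lim]
    if (length(cand) == 0) next
    dawn <- ts[up[k]]
    dusk <- ts[max(cand)]
    len_h <- as.numeric(dusk - dawn, units = "hours")
    if (len_h < min_day_h || len_h > max_day_h) {
      warning("detect_twilights: implausible day length; day skipped")
      next
    }
    res[[length(res) + 1]] <- tibble::tibble(
      date = as.Date(dawn + len_h * 1800, tz = "UTC"),
      dawn_utc = dawn, dusk_utc = dusk
    )
  }
  if (length(res) == 0) {
    return(tibble::tibble(date = as.Date(character()),
                          dawn_utc = as.POSIXct(character(), tz = "UTC"),
                          dusk_utc = as.POSIXct(character(), tz = "UTC")))
  }
  out <- dplyr::bind_rows(res)
  out[!duplicated(out$date), ]
}
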