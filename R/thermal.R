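#' Physiological temperature thresholds for skipjack tuna
#'
#' The extraordinary-event threshold on peritoneal temperature is the red
#' muscle overheating limit (35 C) minus the assumed red-muscle to
#' peritoneal gradient (4 C), i.e. 31 C. Spawning requires water of at
#' least 24 C; sustained water below 18 C is considered lethal.
#'
#' @param t_spawn_C,t_lethal_low_C,t_redmuscle_max_C,gradient_rm_peritoneal_C
#'   Threshold overrides (degrees C).
#' @param boundary_lat_deg Spawning-area boundary latitude (default 25).
#' @param release_min_lat_deg,southward_min_deg Southward-movement filter
#'   parameters (defaults 35 and 0.1).
#' @return List of thresholds, including derived `t_event_C`.
#' @export
physio_thresholds <- function(t_spawn_C = 24,
                              t_lethal_low_C = 18,
                              t_redmuscle_max_C = 35,
                              gradient_rm_peritoneal_C = 4,
                              boundary_lat_deg = 25,
                              release_min_lat_deg = 35,
                              southward_min_deg = 0.1) {
  t_event <- t_redmuscle_max_C - gradient_rm_peritoneal_C
  stopifnot(t_lethal_low_C < t_spawn_C, t_spawn_C < t_event)
  list(
    t_spawn_C = t_spawn_C,
    t_lethal_low_C = t_lethal_low_C,
    t_redmuscle_max_C = t_redmuscle_max_C,
    gradient_rm_peritoneal_C = gradient_rm_peritoneal_C,
    t_event_C = t_event,
    boundary_lat_deg = boundary_lat_deg,
    release_min_lat_deg = release_min_lat_deg,
    southward_min_deg = southward_min_deg
  )
}

#' Daily thermal summary of a tag series
#'
#' Days are bounded by UTC midnight. Water temperature is the daily mean
#' of the external sensor; body temperature is the daily maximum of the
#' internal sensor; SST is the shallow-water mean from [tag_sst_daily()].
#'
#' @param tag_series Tibble with `timestamp_utc`, `depth_m`,
#'   `temp_internal_c`, `temp_external_c`.
#' @param depth_cutoff_m Cutoff for the SST column (default 5 m).
#' @return Tibble: `date`, `mean_water_C`, `max_body_C`, `sst_C`,
#'   `n_samples`.
#' @export
daily_thermal_summary <- function(tag_series, depth_cutoff_m = 5) {
  stopifnot(nrow(tag_series) > 0)
  daily <- tag_series |>
    dplyr::mutate(date = as.Date(.data$timestamp_utc, tz = "UTC")) |>
    dplyr::group_by(date) |>
    dplyr::summarise(
      mean_water_C = mean(.data$temp_external_c),
      max_body_C = max(.data$temp_internal_c),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
  sst <- tag_sst_daily(tag_series, depth_cutoff_m)
  daily |>
    dplyr::left_join(
      dplyr::select(sst, "date", sst_C = "sst_c"), by = "date"
    ) |>
    dplyr::select("date", "mean_water_C", "max_body_C", "sst_C", "n_samples")
}

#' Monthly water temperature experienced, by movement group
#'
#' Pools daily mean water temperatures over individuals within movement
#' group and calendar month, and flags months against the spawning
#' (mean < 24 C: unsuitable) and lethal (mean <= 18 C) thresholds.
#'
#' @param daily_thermal_tables List of tibbles from
#'   [daily_thermal_summary()], one per fish.
#' @param group_labels Character vector of group labels, one per table.
#' @param thresholds List from [physio_thresholds()].
#' @return Tibble: `month` (1-12), `group`, `mean_C`, `sd_C`, `n_days`,
#'   `below_spawn` (mean < spawning threshold), `at_lethal_limit`
#'   (mean <= lethal threshold).
#' @export
monthly_experienced <- function(daily_thermal_tables, group_labels,
                                thresholds = physio_thresholds()) {
  stopifnot(length(daily_thermal_tables) == length(group_labels))
  combined <- dplyr::bind_rows(
    lapply(seq_along(daily_thermal_tables), function(i) {
      dplyr::mutate(daily_thermal_tables[[i]], group = group_labels[i])
    })
  )
  combined |>
    dplyr::mutate(month = as.integer(format(.data$date, "%m"))) |>
    dplyr::group_by(.data$month, .data$group) |>
    dplyr::summarise(
      mean_C = mean(.data$mean_water_C),
      sd_C = stats::sd(.data$mean_water_C),
      n_days = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      below_spawn = .data$mean_C < thresholds$t_spawn_C,
      at_lethal_limit = .data$mean_C <= thresholds$t_lethal_low_C
    ) |>
    dplyr::arrange(.data$group, .data$month)
}

#' Detect extraordinary body-temperature events
#'
#' Maximal runs of samples with internal temperature at or above the
#' event threshold (31 C by default); runs separated by less than
#' `merge_gap_min` are merged, runs shorter than `min_duration_min` are
#' discarded. Each event's onset is traced back along the smoothed
#' temperature rise by [event_onset()], and the onset is expressed in
#' local solar hour using the day's estimated longitude when a track is
#' supplied.
#'
#' @param tag_series Tibble with `timestamp_utc` and `temp_internal_c`.
#' @param thresholds List from [physio_thresholds()].
#' @param merge_gap_min Merge runs separated by less than this (default 10).
#' @param min_duration_min Discard events above threshold for less than
#'   this (default 1).
#' @param track Optional tibble with `date` and `lon` for local-hour
#'   conversion; events keep `onset_local_solar_hour = NA` without one.
#' @param smooth_window_min Smoothing window for onset tracing (default 5).
#' @return Tibble of `ThermalEvent`s: `onset_utc`, `crossing_utc`,
#'   `peak_C`, `peak_utc`, `end_utc`, `duration_above_min`,
#'   `onset_local_solar_hour`.
#' @export
detect_thermal_events <- function(tag_series,
                                  thresholds = physio_thresholds(),
                                  merge_gap_min = 10,
                                  min_duration_min = 1,
                                  track = NULL,
                                  smooth_window_min = 5) {
  temp <- tag_series$temp_internal_c
  ts <- tag_series$timestamp_utc
  stopifnot(!is.null(temp))
  n <- length(temp)
  empty <- tibble::tibble(
    onset_utc = as.POSIXct(character(), tz = "UTC"),
    crossing_utc = as.POSIXct(character(), tz = "UTC"),
    peak_C = numeric(),
    peak_utc = as.POSIXct(character(), tz = "UTC"),
    end_utc = as.POSIXct(character(), tz = "UTC"),
    duration_above_min = numeric(),
    onset_local_solar_hour = numeric()
  )
  above <- temp >= thresholds$t_event_C
  if (!any(above)) return(empty)
  sampling_s <- as.numeric(stats::median(diff(as.numeric(ts))))

  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by a short gap
  if (nrow(runs) > 1) {
    gap_samples <- merge_gap_min * 60 / sampling_s
    merged <- runs[1, ]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - merged$end[nrow(merged)] - 1 < gap_samples) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  dur_min <- (runs$end - runs$start + 1) * sampling_s / 60
  runs <- runs[dur_min >= min_duration_min, , drop = FALSE]
  if (nrow(runs) == 0) return(empty)

  sm <- smooth_series(temp, smooth_window_min, sampling_s)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    i1 <- runs$start[i]
    i2 <- runs$end[i]
    ipk <- i1 - 1 + which.max(temp[i1:i2])
    onset_i <- event_onset_index(temp, sm, i1, sampling_s,
                                 max_back_min = 120)
    hour <- NA_real_
    if (!is.null(track)) {
      j <- which(track$date == as.Date(ts[onset_i], tz = "UTC"))
      if (length(j) == 0) {
        j <- which.min(abs(as.numeric(track$date -
                                        as.Date(ts[onset_i], tz = "UTC"))))
      }
      if (length(j) > 0 && !is.na(track$lon[j[1]])) {
        hour <- local_solar_hour(ts[onset_i], track$lon[j[1]])
      }
    }
    tibble::tibble(
      onset_utc = ts[onset_i],
      crossing_utc = ts[i1],
      peak_C = temp[ipk],
      peak_utc = ts[ipk],
      end_utc = ts[i2],
      duration_above_min = (i2 - i1 + 1) * sampling_s / 60,
      onset_local_solar_hour = hour
    )
  })
  dplyr::bind_rows(out)
}

#' Trace an event onset backward from its threshold crossing
#'
#' Walks backward from the first sample at or above the threshold along
#' the smoothed (centered moving average) internal-temperature series
#' while the temperature is still rising, bounded at 120 minutes before
#' the crossing; the onset is then refined to the first sample where the
#' raw rise begins.
#'
#' @param tag_series Tibble with `timestamp_utc`, `temp_internal_c`.
#' @param crossing_utc POSIXct of the threshold crossing (must be a
#'   sample time).
#' @param smooth_window_min Smoothing window in minutes (default 5).
#' @return POSIXct onset time.
#' @export
event_onset <- function(tag_series, crossing_utc, smooth_window_min = 5) {
  ts <- tag_series$timestamp_utc
  i1 <- which(ts == crossing_utc)
  if (length(i1) == 0) stop("event_onset: crossing time not in series")
  sampling_s <- as.numeric(stats::median(diff(as.numeric(ts))))
  sm <- smooth_series(tag_series$temp_internal_c, smooth_window_min,
                      sampling_s)
  ts[event_onset_index(tag_series$temp_internal_c, sm, i1[1], sampling_s,
                       max_back_min = 120)]
}

smooth_series <- function(x, window_min, sampling_s) {
  w <- max(1L, round(window_min * 60 / sampling_s))
  if (w %% 2 == 0) w <- w + 1L
  sm <- zoo::rollmean(x, w, fill = NA, align = "center")
  sm[is.na(sm)] <- x[is.na(sm)]
  sm
}

event_onset_index <- function(raw, sm, i_cross, sampling_s,
                              max_back_min = 120, trend_min = 5) {
  i_min <- max(1L, i_cross - round(max_back_min * 60 / sampling_s))
  m <- max(1L, round(trend_min * 60 / sampling_s))
  i <- i_cross
  # still rising (read forward) either sample-to-sample or on the trend
  # scale; the trend term keeps sensor noise from ending the walk early
  # on shallow ramps
  while (i > i_min &&
           (sm[i] - sm[i - 1] > 0 ||
              sm[i] - sm[max(i_min, i - m)] > 0)) {
    i <- i - 1
  }
  # refine: skip the leading tail the smoother smeared over flat data
  while (i < i_cross && !(raw[i + 1] > raw[i])) i <- i + 1
  i
}

#' Inter-event interval statistics
#'
#' @param events Tibble from [detect_thermal_events()] (sorted by onset).
#' @return List with `intervals_days` (successive onset-to-onset
#'   differences) and `summary` (min, median, max), empty with fewer than
#'   two events.
#' @export
event_interval_stats <- function(events) {
  if (nrow(events) < 2) {
    return(list(intervals_days = numeric(),
                summary = c(min = NA_real_, median = NA_real_,
                            max = NA_real_)))
  }
  onsets <- sort(events$onset_utc)
  iv <- as.numeric(diff(onsets), units = "days")
  list(
    intervals_days = iv,
    summary = c(min = min(iv), median = stats::median(iv), max = max(iv))
  )
}

#' Histogram of event onset local solar hours
#'
#' @param events Tibble from [detect_thermal_events()].
#' @return Integer vector of 24 counts named "0".."23"; sums to the
#'   number of events with a known onset hour.
#' @export
onset_hour_histogram <- function(events) {
  h <- floor(events$onset_local_solar_hour) %% 24
  h <- h[!is.na(h)]
  counts <- tabulate(h + 1, nbins = 24)
  names(counts) <- as.character(0:23)
  counts
}
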