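TAG_SERIES_COLS <- c("timestamp_utc", "depth_m", "temp_internal_c",
                     "temp_external_c", "light")

#' Read an archival-tag sensor series from CSV
#'
#' Required columns: `timestamp_utc` (ISO-8601, UTC), `depth_m`,
#' `temp_internal_c`, `temp_external_c`, `light`. Rows are sorted by
#' time; duplicate timestamps are an error; gaps are tolerated.
#'
#' @param path CSV file path.
#' @return Tibble sorted by `timestamp_utc`.
#' @export
read_tag_series <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(TAG_SERIES_COLS, names(df))
  if (length(missing) > 0) {
    stop("read_tag_series: missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$timestamp_utc <- as.POSIXct(df$timestamp_utc, tz = "UTC")
  df <- dplyr::arrange(df, .data$timestamp_utc)
  if (anyDuplicated(df$timestamp_utc)) {
    stop("read_tag_series: duplicate timestamps")
  }
  df[, TAG_SERIES_COLS]
}

#' Write an archival-tag sensor series to CSV
#'
#' @param tag_series Tibble with the standard series columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tag_series <- function(tag_series, path) {
  out <- tag_series[, TAG_SERIES_COLS]
  out$timestamp_utc <- format(out$timestamp_utc, "%Y-%m-%dT%H:%M:%SZ",
                              tz = "UTC")
  readr::write_csv(out, path)
  invisible(path)
}

#' Read / write a flat pipeline configuration file
#'
#' One `key = value` pair per line; `#` starts a comment. Values are
#' parsed as numeric, logical (`true`/`false`), or strings; comma-separated
#' values become vectors. Unknown keys (not in [default_pipeline_config()])
#' are rejected.
#'
#' @param path Config file path.
#' @param config Named list to write.
#' @return `read_pipeline_config` returns the default configuration with
#'   the file's overrides applied.
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- default_pipeline_config()
  cfg <- defaults
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("read_pipeline_config: malformed line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% names(defaults)) {
      stop("read_pipeline_config: unknown key: ", key)
    }
    cfg[[key]] <- parse_config_value(val)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  fmt <- vapply(config, function(v) {
    paste(vapply(v, function(x) {
      if (is.logical(x)) tolower(as.character(x)) else as.character(x)
    }, character(1)), collapse = ", ")
  }, character(1))
  writeLines(paste(names(config), "=", fmt), path)
  invisible(path)
}

parse_config_value <- function(val) {
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  parsed <- lapply(parts, function(p) {
    if (tolower(p) %in% c("true", "false")) {
      return(tolower(p) == "true")
    }
    num <- suppressWarnings(as.numeric(p))
    if (!is.na(num)) return(num)
    p
  })
  if (length(parsed) == 1) parsed[[1]] else unlist(parsed)
}

#' Default pipeline configuration
#'
#' All tunable parameters of the end-to-end synthetic-scenario pipeline:
#' simulator settings (scenario, cohort size, deployment dates), SST-field
#' calibration, geolocation observation sds and equinox window, event
#' detection guards, physiological thresholds, and the master seed.
#'
#' @return Named list (flat; serializable via [write_pipeline_config()]).
#' @export
default_pipeline_config <- function() {
  list(
    scenario = "resident",          # resident | migrant
    n_tags = 3,
    n_days = 250,
    release_lat = 36.7,
    release_lon = 141.4,
    release_date = "2021-10-25",
    thermal_excess_C = 3,
    with_events = FALSE,
    sampling_s = 30,
    # SST field calibration
    sst_base_C = 24.85,
    sst_lat_ref = 30,
    sst_gradient_C_per_deg = 0.5,
    sst_seasonal_amp_C = 4,
    sst_peak_doy = 228,
    sst_resolution_deg = 1,
    # geolocation
    light_threshold = 0.3,
    twilight_smooth_min = 10,
    sun_alt_deg = -8.1,
    equinox_decl_min_deg = 3,
    obs_sd_lon = 0.5,
    obs_sd_lat = 1.0,
    obs_sd_lat_equinox = 20,
    sd_sst = 0.3,
    sigma_kms = -1,                  # -1: estimate by maximum likelihood
    # thermal events
    merge_gap_min = 10,
    min_duration_min = 1,
    onset_smooth_min = 5,
    # thresholds
    t_spawn_C = 24,
    t_lethal_low_C = 18,
    t_redmuscle_max_C = 35,
    gradient_rm_peritoneal_C = 4,
    boundary_lat_deg = 25,
    seed = 1
  )
}
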