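#' Daily tag-side sea-surface temperature
#'
#' SST experienced by the fish, taken as the mean external temperature
#' over samples shallower than `depth_cutoff_m` (default 5 m) within each
#' UTC day. Days with no qualifying samples are omitted.
#'
#' @param tag_series Tibble with `timestamp_utc`, `depth_m`,
#'   `temp_external_c`.
#' @param depth_cutoff_m Depth cutoff in metres (> 0, default 5).
#' @return Tibble: `date`, `sst_c`, `n_samples`.
#' @export
tag_sst_daily <- function(tag_series, depth_cutoff_m = 5) {
  stopifnot(depth_cutoff_m > 0)
  tag_series |>
    dplyr::filter(.data$depth_m <= depth_cutoff_m) |>
    dplyr::mutate(date = as.Date(.data$timestamp_utc, tz = "UTC")) |>
    dplyr::group_by(date) |>
    dplyr::summarise(
      sst_c = mean(.data$temp_external_c),
      n_samples = dplyr::n(),
      .groups = "drop"
    )
}
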