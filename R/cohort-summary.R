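#' Filter dart-tag records to southward movers from the northern habitat
#'
#' Keeps recaptured records released at or north of `release_min_lat`
#' whose recapture latitude lies at least `southward_min_deg` south of
#' the release latitude. Unrecaptured records are dropped. Idempotent.
#'
#' @param records Tibble of PDT records with `release_lat` and
#'   `recapture_lat`.
#' @param release_min_lat Minimum release latitude (default 35).
#' @param southward_min_deg Minimum southward displacement (default 0.1).
#' @return Filtered tibble.
#' @export
filter_southward <- function(records, release_min_lat = 35,
                             southward_min_deg = 0.1) {
  records |>
    dplyr::filter(
      !is.na(.data$recapture_lat),
      .data$release_lat >= release_min_lat,
      .data$release_lat - .data$recapture_lat >= southward_min_deg
    )
}

#' Recapture rate
#'
#' @param n_released Number released (> 0).
#' @param n_recaptured Number recaptured (between 0 and `n_released`).
#' @return Percent recaptured (full precision; compare tables at 1 dp).
#' @export
#' @examples
#' recapture_rate(1029, 257) # 24.97...
recapture_rate <- function(n_released, n_recaptured) {
  if (any(n_released <= 0)) stop("recapture_rate: no releases")
  if (any(n_recaptured < 0 | n_recaptured > n_released)) {
    stop("recapture_rate: recaptures outside [0, released]")
  }
  100 * n_recaptured / n_released
}

#' Pooled spawning-potential proportion
#'
#' @param n_sp,n_res Group counts (sum > 0).
#' @return Percent `100 * n_sp / (n_sp + n_res)` (full precision; compare
#'   tables at 2 dp).
#' @export
#' @examples
#' pooled_proportion(18, 63) # 22.22...
pooled_proportion <- function(n_sp, n_res) {
  if (any(n_sp + n_res <= 0)) stop("pooled_proportion: empty group")
  100 * n_sp / (n_sp + n_res)
}

#' Weighted mean and sd of yearly proportions
#'
#' Weighted mean and population-form weighted standard deviation,
#' typically with yearly recapture counts as weights — in which case the
#' weighted mean equals the pooled proportion algebraically.
#'
#' @param yearly_props Proportions (any scale) per year.
#' @param weights Nonnegative weights, same length, positive sum.
#' @return Named vector: `mean`, `sd`.
#' @export
weighted_proportion <- function(yearly_props, weights) {
  stopifnot(length(yearly_props) == length(weights))
  if (any(weights < 0)) stop("weighted_proportion: negative weight")
  sw <- sum(weights)
  if (sw <= 0) stop("weighted_proportion: weights sum to zero")
  m <- sum(weights * yearly_props) / sw
  s <- sqrt(sum(weights * (yearly_props - m)^2) / sw)
  c(mean = m, sd = s)
}

#' Decadal movement-group counts from dart-tag records
#'
#' Records are assigned to decades by release date (1980s = 1980-1989,
#' ...), and classified by recapture latitude against the boundary.
#'
#' @param records Tibble of (already southward-filtered) PDT records with
#'   `release_date` and `recapture_lat`.
#' @param boundary_deg Spawning boundary latitude (default 25).
#' @return Tibble: `decade` (e.g. `"1980s"`), `n_sp`, `n_res`,
#'   `pooled_pct`, `min_recapture_lat`.
#' @export
decadal_group_counts <- function(records, boundary_deg = 25) {
  if (nrow(records) == 0) {
    return(tibble::tibble(decade = character(), n_sp = integer(),
                          n_res = integer(), pooled_pct = numeric(),
                          min_recapture_lat = numeric()))
  }
  records |>
    dplyr::mutate(
      decade = paste0(
        (as.integer(format(as.Date(.data$release_date), "%Y")) %/% 10) * 10,
        "s"
      ),
      sp = .data$recapture_lat < boundary_deg
    ) |>
    dplyr::group_by(.data$decade) |>
    dplyr::summarise(
      n_sp = sum(.data$sp),
      n_res = sum(!.data$sp),
      pooled_pct = pooled_proportion(sum(.data$sp), sum(!.data$sp)),
      min_recapture_lat = min(.data$recapture_lat),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$decade)
}
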