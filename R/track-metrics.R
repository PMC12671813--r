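#' Daily movement steps from a track
#'
#' One step per pair of consecutive calendar days; gaps in the track
#' produce no step (no interpolation).
#'
#' @param track Tibble with `date`, `lat`, `lon`.
#' @return Tibble of `DailyStep`s: `date` (step end date), `distance_km`,
#'   `bearing_deg` (NA for zero-length steps).
#' @export
daily_steps <- function(track) {
  stopifnot(nrow(track) >= 2)
  track <- dplyr::arrange(track, .data$date)
  i <- which(diff(as.numeric(track$date)) == 1)
  p1 <- cbind(track$lat[i], track$lon[i])
  p2 <- cbind(track$lat[i + 1], track$lon[i + 1])
  dist <- great_circle_km(p1, p2)
  brg <- rep(NA_real_, length(i))
  nz <- dist > 1e-9
  if (any(nz)) {
    brg[nz] <- initial_bearing_deg(p1[nz, , drop = FALSE],
                                   p2[nz, , drop = FALSE])
  }
  tibble::tibble(
    date = track$date[i + 1],
    distance_km = dist,
    bearing_deg = brg
  )
}

#' Radar-chart summary of daily steps
#'
#' Bearings are binned into `n_sectors` equal sectors centered on 0,
#' 360/n, ... degrees (so the "north" sector straddles 0).
#'
#' @param steps Tibble from [daily_steps()].
#' @param n_sectors Number of sectors (>= 4, default 16).
#' @return Tibble: `sector_center_deg`, `count`, `mean_distance_km`.
#'   Counts sum to the number of steps with a defined bearing.
#' @export
radar_summary <- function(steps, n_sectors = 16) {
  stopifnot(n_sectors >= 4)
  steps <- steps[!is.na(steps$bearing_deg), ]
  centers <- (0:(n_sectors - 1)) * 360 / n_sectors
  if (nrow(steps) == 0) {
    return(tibble::tibble(sector_center_deg = numeric(), count = integer(),
                          mean_distance_km = numeric()))
  }
  width <- 360 / n_sectors
  sector <- (floor((steps$bearing_deg + width / 2) / width)) %% n_sectors
  steps |>
    dplyr::mutate(sector_center_deg = centers[sector + 1]) |>
    dplyr::group_by(.data$sector_center_deg) |>
    dplyr::summarise(
      count = dplyr::n(),
      mean_distance_km = mean(.data$distance_km),
      .groups = "drop"
    )
}

#' Days at liberty
#'
#' Exclusive calendar-day difference, recapture minus release.
#'
#' @param release_date,recapture_date Dates (or coercible).
#' @return Integer days.
#' @export
#' @examples
#' days_at_liberty("2021-10-25", "2022-04-28") # 185
days_at_liberty <- function(release_date, recapture_date) {
  release_date <- as.Date(release_date)
  recapture_date <- as.Date(recapture_date)
  if (any(recapture_date < release_date)) {
    stop("days_at_liberty: recapture precedes release")
  }
  as.integer(recapture_date - release_date)
}

#' Classify a fish into the spawning-potential or residence group
#'
#' A fish belongs to the spawning-potential group when it moved into the
#' warm area south of the boundary: for an archival-tag track the basis is
#' the minimum daily estimated latitude over the deployment; for a
#' dart-tag record it is the recapture latitude. The comparison is strict
#' (`< boundary`), so a fish sitting exactly on the boundary is residence.
#'
#' @param latitudes Numeric latitudes: a track's daily latitudes, or a
#'   single recapture latitude.
#' @param boundary_deg Boundary latitude (default 25).
#' @param basis `"track_minimum_latitude"` or `"recapture_latitude"`
#'   (metadata recorded in the result).
#' @return A `movement_group` list: `label` (`"spawning_potential"` or
#'   `"residence"`), `basis`, `minimum_latitude_deg`.
#' @export
classify_movement_group <- function(latitudes, boundary_deg = 25,
                                    basis = c("track_minimum_latitude",
                                              "recapture_latitude")) {
  basis <- match.arg(basis)
  latitudes <- latitudes[!is.na(latitudes)]
  if (length(latitudes) == 0) stop("classify_movement_group: no latitudes")
  min_lat <- min(latitudes)
  structure(
    list(
      label = if (min_lat < boundary_deg) "spawning_potential" else "residence",
      basis = basis,
      minimum_latitude_deg = min_lat
    ),
    class = "movement_group"
  )
}

#' @export
print.movement_group <- function(x, ...) {
  cat(sprintf("movement group: %s (basis %s, min lat %.2f)\n",
              x$label, x$basis, x$minimum_latitude_deg))
  invisible(x)
}
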