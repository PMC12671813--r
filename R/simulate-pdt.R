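#' Simulate a plastic-dart-tag release/recapture cohort
#'
#' Fixture generator for the mark-recapture summaries: releases are drawn
#' north of 35 degrees N in the study region; each release is recaptured
#' with probability `recapture_rate`, and each recapture lands south of
#' the 25 degree N spawning boundary with probability
#' `p_spawning_potential` (otherwise between 25 N and just south of the
#' release latitude, so every recapture passes the southward filter).
#'
#' @param n_per_year Releases per year.
#' @param years Integer vector of release years.
#' @param p_spawning_potential Probability a recapture is south of 25 N.
#' @param recapture_rate Probability a release is recaptured.
#' @param seed Integer seed.
#' @return Tibble of PDT records: `tag_id`, `release_date`, `release_lat`,
#'   `release_lon`, `fl_release_cm`, `recapture_date`, `recapture_lat`,
#'   `recapture_lon` (NA when not recaptured).
#' @export
simulate_pdt_cohort <- function(n_per_year, years,
                                p_spawning_potential = 0.22,
                                recapture_rate = 0.1,
                                seed = 1L) {
  if (length(years) == 0) stop("simulate_pdt_cohort: empty years")
  stopifnot(p_spawning_potential >= 0, p_spawning_potential <= 1,
            recapture_rate >= 0, recapture_rate <= 1)
  n <- n_per_year * length(years)
  withr_seed(seed, {
    year <- rep(years, each = n_per_year)
    release_date <- as.Date(paste0(year, "-01-01")) +
      sample(0:364, n, replace = TRUE)
    release_lat <- stats::runif(n, 35, 41)
    release_lon <- stats::runif(n, 141, 149)
    fl <- stats::rnorm(n, 45, 7)
    recaptured <- stats::runif(n) < recapture_rate
    south <- stats::runif(n) < p_spawning_potential
    recapture_lat <- ifelse(
      south,
      stats::runif(n, 2, 24.9),
      stats::runif(n, 25, release_lat - 0.2)
    )
    recapture_lat[!recaptured] <- NA_real_
    recapture_lon <- ifelse(recaptured, stats::runif(n, 130, 160), NA_real_)
    liberty <- sample(5:400, n, replace = TRUE)
    tibble::tibble(
      tag_id = sprintf("pdt%05d", seq_len(n)),
      release_date = release_date,
      release_lat = release_lat,
      release_lon = release_lon,
      fl_release_cm = round(pmax(30, fl), 1),
      recapture_date = dplyr::if_else(recaptured, release_date + liberty,
                                      as.Date(NA)),
      recapture_lat = recapture_lat,
      recapture_lon = recapture_lon
    )
  })
}
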