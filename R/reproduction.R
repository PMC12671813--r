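#' Gonadal index
#'
#' GI = Gw / FL^3 x 10^4, with gonad weight in grams and fork length in
#' centimetres.
#'
#' @param gw_g Gonad weight (g), >= 0.
#' @param fl_cm Fork length (cm), > 0.
#' @return GI (vectorised).
#' @export
#' @examples
#' gonadal_index(1, 10) # 10
gonadal_index <- function(gw_g, fl_cm) {
  if (any(fl_cm <= 0)) stop("gonadal_index: fork length must be positive")
  if (any(gw_g < 0)) stop("gonadal_index: gonad weight must be >= 0")
  gw_g / fl_cm^3 * 1e4
}

#' Gonadosomatic index
#'
#' GSI = Gw / Bw x 10^2, both weights in grams.
#'
#' @param gw_g Gonad weight (g), >= 0.
#' @param bw_g Body weight (g), > 0.
#' @return GSI (vectorised).
#' @export
gonadosomatic_index <- function(gw_g, bw_g) {
  if (any(bw_g <= 0)) stop("gonadosomatic_index: body weight must be positive")
  if (any(gw_g < 0)) stop("gonadosomatic_index: gonad weight must be >= 0")
  gw_g / bw_g * 100
}

MAGO_CODES <- c("Pn", "Ca", "Py", "Sy", "Ty", "GVM", "Hyd")
YOLKED_CODES <- c("Py", "Sy", "Ty")

#' Assign an ovarian maturity phase from histology
#'
#' Decision rules, applied in order: (1) postovulatory follicles present,
#' or the most advanced oocytes in germinal vesicle migration or
#' hydrated, imply spawning capable; (2) perinucleolus or cortical
#' alveolar oocytes imply immature; (3) yolked oocytes with relative
#' intensity of atresia >= 50% imply regression; (4) yolked oocytes
#' otherwise (atresia < 50% or absent) imply developmental.
#'
#' @param mago Most advanced group of oocytes: one of `"Pn"`, `"Ca"`,
#'   `"Py"`, `"Sy"`, `"Ty"`, `"GVM"`, `"Hyd"`.
#' @param pof_present Logical: postovulatory follicles observed.
#' @param ia_pct Relative intensity of atresia, percent in `[0, 100]`, or
#'   `NA` when not assessed (treated as < 50).
#' @return One of `"immature"`, `"developmental"`, `"regression"`,
#'   `"spawning_capable"` (vectorised).
#' @export
#' @examples
#' stage_maturity("Ca", FALSE, NA)  # immature
#' stage_maturity("Sy", TRUE, 20)   # spawning_capable
stage_maturity <- function(mago, pof_present, ia_pct = NA_real_) {
  n <- max(length(mago), length(pof_present), length(ia_pct))
  mago <- rep_len(as.character(mago), n)
  pof_present <- rep_len(as.logical(pof_present), n)
  ia_pct <- rep_len(as.numeric(ia_pct), n)
  bad <- !(mago %in% MAGO_CODES)
  if (any(bad)) {
    stop("stage_maturity: unknown MAGO code: ",
         paste(unique(mago[bad]), collapse = ", "))
  }
  if (any(!is.na(ia_pct) & (ia_pct < 0 | ia_pct > 100))) {
    stop("stage_maturity: ia_pct outside [0, 100]")
  }
  ifelse(
    pof_present | mago %in% c("GVM", "Hyd"), "spawning_capable",
    ifelse(
      mago %in% c("Pn", "Ca"), "immature",
      ifelse(!is.na(ia_pct) & ia_pct >= 50, "regression", "developmental")
    )
  )
}

#' Cohort maturity summary table
#'
#' Stages each sample and summarises GI (and GSI where body weight is
#' available) by phase: n, mean +/- sample sd (sd undefined for
#' single-sample groups), and range. Samples with GI below the minimum GI
#' observed among mature (non-immature) phases are flagged
#' (`below_mature_min_gi`) in the returned staged table.
#'
#' @param samples Tibble of gonad samples: `fl_cm`, `gw_g`, `mago`,
#'   `pof_present`, optional `bw_g`, `ia_pct`, `sample_id`.
#' @return List with `staged` (input plus `gi`, `gsi`, `phase`,
#'   `below_mature_min_gi`) and `summary` (per-phase table).
#' @export
cohort_maturity_table <- function(samples) {
  staged <- samples |>
    dplyr::mutate(
      gi = gonadal_index(.data$gw_g, .data$fl_cm),
      gsi = if ("bw_g" %in% names(samples)) {
        ifelse(is.na(.data$bw_g), NA_real_,
               .data$gw_g / .data$bw_g * 100)
      } else {
        NA_real_
      },
      phase = stage_maturity(
        .data$mago, .data$pof_present,
        if ("ia_pct" %in% names(samples)) .data$ia_pct else NA_real_
      )
    )
  mature_gi <- staged$gi[staged$phase != "immature"]
  min_mature <- if (length(mature_gi)) min(mature_gi) else NA_real_
  staged$below_mature_min_gi <- !is.na(min_mature) & staged$gi < min_mature

  summary <- staged |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_gi = mean(.data$gi),
      sd_gi = ifelse(dplyr::n() > 1, stats::sd(.data$gi), NA_real_),
      min_gi = min(.data$gi),
      max_gi = max(.data$gi),
      mean_gsi = mean(.data$gsi, na.rm = TRUE),
      sd_gsi = ifelse(sum(!is.na(.data$gsi)) > 1,
                      stats::sd(.data$gsi, na.rm = TRUE), NA_real_),
      .groups = "drop"
    )
  list(staged = staged, summary = summary)
}
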