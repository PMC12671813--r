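#!/usr/bin/env Rscript
# Gonadal maturity: verify the histology-based staging rules against the
# published criteria combinations and recover phase-conditional gonadal
# index means from a synthetic cohort.

library(skipjacktag)
dir.create("results", showWarnings = FALSE)
extdata <- function(f) system.file("extdata", f, package = "skipjacktag")

crit <- readr::read_csv(extdata("maturity_staging_criteria.csv"),
                        show_col_types = FALSE)
crit$staged <- stage_maturity(crit$mago, crit$pof_present, crit$ia_pct)
readr::write_csv(crit, "results/staging_criteria_check.csv")
message(sum(crit$staged == crit$stage), " of ", nrow(crit),
        " published criteria rows stage correctly.")

# synthetic cohort with phase-conditional GI structure: immature fish
# around GI 0.94 (the release-sample mean) and regressing fish around
# 2.84, as observed at recapture
set.seed(61)
n <- 50
cohort <- tibble::tibble(
  sample_id = sprintf("s%03d", 1:(2 * n)),
  fl_cm = runif(2 * n, 45, 60),
  mago = rep(c("Ca", "Py"), each = n),
  pof_present = FALSE,
  ia_pct = rep(c(NA, 60), each = n)
)
gi_target <- rep(c(0.94, 2.84), each = n) + rnorm(2 * n, 0, 0.13)
cohort$gw_g <- gi_target * cohort$fl_cm^3 / 1e4
cohort$bw_g <- 30 * cohort$fl_cm^2   # crude length-weight scaling

out <- cohort_maturity_table(cohort)
readr::write_csv(out$summary, "results/maturity_cohort_summary.csv")
msg <- sprintf("%s: n=%d, mean GI %.2f",
               out$summary$phase, out$summary$n, out$summary$mean_gi)
message("Cohort summary - ", paste(msg, collapse = "; "),
        ". All immature samples fall below the minimum mature GI (flagged: ",
        sum(out$staged$below_mature_min_gi), " samples).")
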