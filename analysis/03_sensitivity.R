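#!/usr/bin/env Rscript
# Step 3 — heterogeneity and pleiotropy diagnostics.
#
# Cochran Q for each instrument set (and for magnesium after dropping the
# SHROOM3 SNP that drives its heterogeneity), plus the MR-Egger intercepts
# that test for directional pleiotropy. Writes results/diagnostics.tsv.

suppressPackageStartupMessages({
  library(mrminerals)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

sets <- list(
  calcium = example_instruments("calcium"),
  magnesium = example_instruments("magnesium"),
  `magnesium minus rs13146355` = apply_exclusion(
    example_instruments("magnesium"), pleiotropy_exclusions()$shroom3
  )
)

diagnostics <- bind_rows(lapply(names(sets), function(nm) {
  s <- sets[[nm]]
  ivw <- mr_ivw(s)
  egger <- mr_egger(s)
  tibble::tibble(
    set = nm, n_snps = n_snps(s),
    q = ivw$q_statistic, q_df = ivw$q_df, q_p = ivw$q_p,
    egger_intercept = egger$egger_intercept$estimate,
    intercept_ci_low = egger$egger_intercept$ci_low,
    intercept_ci_high = egger$egger_intercept$ci_high,
    intercept_p = egger$egger_intercept$p_value
  )
}))

readr::write_tsv(diagnostics, "results/diagnostics.tsv")

cat("Heterogeneity and directional-pleiotropy diagnostics\n")
cat("----------------------------------------------------\n")
print(as.data.frame(diagnostics), digits = 3)
cat("\nCalcium instruments are homogeneous (Q p = ",
    sprintf("%.2f", diagnostics$q_p[1]),
    "); magnesium shows suggestive heterogeneity (p = ",
    sprintf("%.2f", diagnostics$q_p[2]),
    ")\nthat disappears once rs13146355 is removed (p = ",
    sprintf("%.2f", diagnostics$q_p[3]), ").\n", sep = "")
cat("Neither Egger intercept differs from zero, so there is no evidence\n")
cat("of directional pleiotropy — though with 6-7 SNPs this test has low power.\n")
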