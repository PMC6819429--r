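#!/usr/bin/env Rscript
# Step 4 — statistical power of the design.
#
# Binary-outcome MR power for the heart-failure GWAS (394,156 participants,
# 6,504 cases): the smallest odds ratios detectable with 80% power given
# each mineral's instrument R-squared, and the post-hoc power to detect the
# observed OR of 0.89. Writes results/power.tsv.

suppressPackageStartupMessages({
  library(mrminerals)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

n_total <- 394156
n_cases <- 6504
r2 <- c(calcium = 0.009, magnesium = 0.016)

power_tbl <- bind_rows(lapply(names(r2), function(mineral) {
  sol <- detectable_or(n_total, n_cases, r2[[mineral]], target_power = 0.8)
  tibble::tibble(
    mineral = mineral,
    r_squared = r2[[mineral]],
    detectable_or_risk = sol$or_risk,
    detectable_or_protective = sol$or_protective,
    posthoc_power_or_0.89 = mr_power_binary(
      power_query(n_total, n_cases, r2[[mineral]], odds_ratio = 0.89)
    )
  )
}))

readr::write_tsv(power_tbl, "results/power.tsv")

cat("Power of the heart-failure outcome sample (alpha = 0.05)\n")
cat("---------------------------------------------------------\n")
print(as.data.frame(power_tbl), digits = 4)
cat(sprintf("\nWith 80%% power the design detects OR %.2f (or %.2f) for calcium and
OR %.2f (or %.2f) for magnesium; the post-hoc power to detect the observed
OR of 0.89 is only %.0f%% (calcium) and %.0f%% (magnesium). A weak true
effect of that size could therefore easily have been missed.\n",
            power_tbl$detectable_or_risk[1], power_tbl$detectable_or_protective[1],
            power_tbl$detectable_or_risk[2], power_tbl$detectable_or_protective[2],
            100 * power_tbl$posthoc_power_or_0.89[1],
            100 * power_tbl$posthoc_power_or_0.89[2]))
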