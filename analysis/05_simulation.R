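#!/usr/bin/env Rscript
# Step 5 — estimator calibration on synthetic summary statistics.
#
# Uses the synthetic two-sample generator (50 calcium-like instruments per
# replicate) to check the estimator suite against known ground truth:
# type-I error and CI coverage of fixed-effect IVW under valid instruments,
# recovery of an injected directional-pleiotropy mean by the Egger
# intercept, and the robustness ordering of the weighted median under 40%
# invalid instruments. Writes results/simulation.tsv.

suppressPackageStartupMessages({
  library(mrminerals)
  library(dplyr)
})

dir.create("results", showWarnings = FALSE)

null_study <- replicate_study(synthetic_config(causal_effect = 0, seed = 11),
                              "ivw", n_replicates = 1000, seed = 11)
cover_study <- replicate_study(synthetic_config(causal_effect = -0.2, seed = 12),
                               "ivw", n_replicates = 2000, seed = 12)

pleio_cfg <- synthetic_config(causal_effect = -0.2, se_outcome_level = 0.001,
                              pleiotropy_mode = "directional",
                              pleiotropy_mean = 0.03, pleiotropy_sd = 0.005,
                              invalid_fraction = 0.4, seed = 88)
ivw_pleio <- replicate_study(pleio_cfg, "ivw", 200, seed = 88)
med_pleio <- replicate_study(
  pleio_cfg, function(s) mr_weighted_median(s, bootstrap_spec(50, 1)),
  n_replicates = 200, seed = 88
)

egger_cfg <- synthetic_config(causal_effect = -0.2,
                              pleiotropy_mode = "directional",
                              pleiotropy_mean = 0.02, pleiotropy_sd = 0.005,
                              invalid_fraction = 1, seed = 13)
egger_intercepts <- vapply(1:500, function(i) {
  cfg_i <- egger_cfg
  cfg_i$seed <- 13L + i
  mr_egger(simulate_instruments(cfg_i))$egger_intercept$estimate
}, numeric(1))

calibration <- bind_rows(
  mutate(null_study$summary, scenario = "null effect, valid instruments",
         .before = 1),
  mutate(cover_study$summary, scenario = "causal -0.2, valid instruments",
         .before = 1),
  mutate(ivw_pleio$summary, scenario = "40% invalid, directional: IVW",
         .before = 1),
  mutate(med_pleio$summary, scenario = "40% invalid, directional: w-median",
         .before = 1)
)
readr::write_tsv(calibration, "results/simulation.tsv")

cat("Estimator calibration against synthetic ground truth\n")
cat("-----------------------------------------------------\n")
print(as.data.frame(calibration), digits = 3)
cat(sprintf("\nType-I error %.3f (nominal 0.05); 95%% CI coverage %.3f.\n",
            null_study$summary$rejection_rate, cover_study$summary$coverage))
cat(sprintf("Under 40%% directionally pleiotropic instruments the weighted
median bias (%.3f) is well below the IVW bias (%.3f).\n",
            med_pleio$summary$mean_bias, ivw_pleio$summary$mean_bias))
cat(sprintf("The Egger intercept recovers the injected pleiotropy mean 0.02
as %.4f (500 replicates).\n", mean(egger_intercepts)))
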