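---
title: "Methods: two-sample Mendelian randomization of serum minerals and heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of serum minerals and heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrminerals)
```

## The question and the design

Observational studies have linked higher serum calcium to cardiovascular
disease and suggested a protective role for magnesium, but such estimates
are vulnerable to confounding and reverse causality. Mendelian
randomization (MR) sidesteps both by using genetic variants as
instrumental variables: alleles are assorted at conception, so a SNP that
raises serum calcium provides a lifelong, confounder-free nudge to the
exposure. In the *two-sample* design the SNP–exposure and SNP–outcome
associations come from non-overlapping studies and are combined purely
through summary statistics.

`mrminerals` implements this design end to end for the question of whether
serum calcium and magnesium concentrations affect the risk of heart
failure. The instruments are the 7 calcium-associated and 6
magnesium-associated SNPs from the largest published GWAS meta-analyses of
these minerals (genome-wide significant, mutually independent at
r² < 0.001, jointly explaining 0.9% and 1.6% of exposure variance); the
outcome associations come from a UK Biobank all-cause heart-failure GWAS
(394,156 participants, 6,504 cases). Both tables are shipped as plain-text
fixtures (`inst/extdata/*_hf.tsv`) and loaded with `example_instruments()`.

An MR estimate is causal under three instrument assumptions: the SNP is
(1) robustly associated with the exposure, (2) independent of
exposure–outcome confounders, and (3) affects the outcome only through the
exposure. The estimator suite exists because assumption (3) — no
horizontal pleiotropy — is untestable SNP by SNP; each robust estimator
relaxes it differently.

## Estimators

Let $\hat\beta_{Xj}, \hat\beta_{Yj}$ be SNP $j$'s per-allele exposure and
outcome (log-odds) effects with standard errors
$\sigma_{Xj}, \sigma_{Yj}$. The per-SNP Wald ratio is
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, with first-order
delta-method standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$ (the exposure
uncertainty is ignored — the NO Measurement Error approximation, justified
here by instrument F-statistics of 31–299). All estimators weight by the
inverse Wald-ratio variance $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.

**IVW** (`mr_ivw()`): $\hat\theta = \sum_j w_j\hat\theta_j / \sum_j w_j$,
algebraically the weighted least-squares slope of $\hat\beta_{Yj}$ on
$\hat\beta_{Xj}$ through the origin. The fixed-effect standard error is
$(\sum_j w_j)^{-1/2}$; the multiplicative random-effects option inflates
it by $\max\{1, \sqrt{Q/(n-1)}\}$. The default is fixed-effect: with 6–7
instruments the heterogeneity estimate is unstable, and for the calcium
set $Q < n-1$ so the floored random-effects model coincides with it
anyway.

**Cochran's Q** (`cochran_q()`):
$Q = \sum_j w_j(\hat\theta_j - \hat\theta)^2$ on $n-1$ df, the standard
heterogeneity diagnostic; large $Q$ flags instruments whose ratios
disagree beyond sampling noise, as rs13146355 (SHROOM3) does in the
magnesium set.

**MR-Egger** (`mr_egger()`): the same regression with a free intercept,
after re-orienting every SNP so $\hat\beta_{Xj} \ge 0$. The intercept
estimates the average directional pleiotropic effect (valid under InSIDE —
instrument strength independent of direct effects); the slope is a
pleiotropy-adjusted causal estimate. Standard errors follow the usual
MR-Egger convention of flooring the residual dispersion at 1 (the WLS
standard error divided by $\min(1, \hat\sigma)$): over-dispersion widens
the intervals, under-dispersion is never allowed to narrow them below the
fixed-effect value. The plain WLS standard error is available via
`se = "plain"`; with 7 under-dispersed calcium instruments it would
roughly halve the intercept's interval, which is why the floored
convention is the default — it is the conservative one and the one the
field's MR-Egger implementations use.

**Weighted median** (`mr_weighted_median()`): order the ratios, place each
at its cumulative-midpoint weight position $p_j = (\sum_{k\le j} w_k) -
w_j/2$ (weights normalized to 1), and linearly interpolate the ratio at
$p = 0.5$. Consistent when valid instruments carry at least 50% of the
weight.

**Weighted mode** (`mr_weighted_mode()`): the argmax of the
normal-kernel-smoothed weighted density of the ratios, evaluated on a
512-point grid over $[\min\hat\theta - h, \max\hat\theta + h]$, with exact
argmax ties broken toward the grid midpoint. Consistent when the largest
group of instruments sharing a causal estimate is valid. The bandwidth is
$h = \phi \cdot 0.9\,\min(\mathrm{sd}, \mathrm{MAD})\, n^{-1/5}$, the
modified Silverman rule of the mode-based-estimation literature, with
$\phi = 1$ by default. A variant deriving the scale from the *weighted*
MAD about the weighted median is available (`bandwidth = "weighted_mad"`);
it typically produces a slightly narrower bandwidth and can move the mode
by a few percent on small panels (on the magnesium set it shifts the OR
from 1.05 to about 1.08). The unweighted min(sd, MAD) convention is the
default because it is the established one.

**Bootstrap standard errors.** The median and mode have no convenient
closed-form variance, so both use a parametric bootstrap: redraw each
SNP's betas from $N(\hat\beta, \sigma)$, recompute the point estimate
(ratios *and* weights), and take the SD over replicates. Defaults: 1,000
replicates, seed 42, configurable through `bootstrap_spec()`. Only the
point estimates of these estimators are treated as reproduction targets;
their interval conventions vary across implementations.

**Per-SD scaling** (`scale_to_or()`): per-unit log-odds are multiplied by
the exposure SD — 0.5 mg/dl for calcium and 0.1 for magnesium (the
magnesium unit is stored verbatim as "mmol/dl" as printed by its source;
the conventional unit would be mmol/L, but only the numeric constant 0.1
enters any computation) — then exponentiated, with 95% intervals from the
normal 1.96 multiplier, which reproduces the published intervals where a
t multiplier would not. P-values come from $\beta/\mathrm{SE}$ and are
scale-invariant.

## Harmonization and exclusion bookkeeping

`harmonize_pair()` aligns an outcome record onto the exposure's effect
allele, flipping the outcome beta when the alleles are swapped and
checking the complementary strand before declaring records incompatible.
Palindromic SNPs (A/T, C/G) with exposure EAF in [0.42, 0.58] cannot be
oriented from strand information and are flagged ambiguous; the policy is
configurable (`flag-keep` default, `strict-drop`). The window and policy
follow common MR practice. The packaged tables carry no other allele —
their outcome lookups were already performed on the exposure orientation —
so records without an `other_allele` pass through as pre-harmonized.
Proxy SNPs (rs10858938 stands in for rs7965584 at r² = 0.95 in the outcome
data) are recorded as metadata only; no LD computation is performed.

Confounder-trait lookups flagged four SNPs, encoded as configuration in
`pleiotropy_exclusions()`: rs780094 (GCKR, metabolic-syndrome traits) and
the kidney-function pair rs3925584 + rs13146355 are classed horizontal and
re-run as IVW sensitivity exclusions; rs448378 (MDS1, blood pressure) is
classed vertical — magnesium lowers blood pressure, so the path is a
mediator — and retained. One quirk is documented rather than resolved: the
narrative accompanying the source data cites "rs12146355" where its
instrument table prints rs13146355; the fixture follows the table.

## The analysis grid

`run_plan(default_plan())` computes all 2 × 4 primary cells plus the three
horizontal-exclusion IVW re-runs, flags significance against the fixed
Bonferroni threshold p < 0.01 (0.05 corrected for two exposures and two
outcomes, applied as a threshold comparison, not a p-value adjustment),
records seed and versions, and serializes `results.tsv` / `results.json`
plus per-set `forest_*.tsv` (per-SNP ORs with a terminal Overall row) and
`scatter_*.tsv` (points plus fitted line) data products. Figure rendering
is deliberately left to the user; the data tables are the canonical
products. Estimator precondition failures (e.g. a 2-SNP set offered to
MR-Egger) become recorded skipped cells, never crashes. The numbered
scripts under `analysis/` are the narrative drivers over these functions.

## Power

`mr_power_binary()` implements the published binary-outcome MR power
formulas. With case fraction $K$, the log-odds effect observable through
the instruments is attenuated to
$b = K\left(\frac{\mathrm{OR}}{1 + K(\mathrm{OR}-1)} - 1\right)$, its
variance is $v = (K(1-K) - b^2)/(N R^2)$, and power is the two-sided
normal tail beyond $z_{1-\alpha/2}$ shifted by $\sqrt{b^2/v}$. The
attenuation is mildly asymmetric in $\mathrm{OR} \leftrightarrow
1/\mathrm{OR}$ — for the calcium design the 80%-power bounds are 1.37 and
0.63, not reciprocals — so `detectable_or()` root-solves the risk and
protective directions separately (tolerance 1e−6, bracket (1, 10] and
[0.05, 1)). The default $\alpha$ is 0.05, the cited calculator's
convention; the analysis' Bonferroni 0.01 is a one-argument switch. Which
of the two entered the published power figures is not stated, and the
reproduction tolerances absorb the difference.

## The synthetic generator

`simulate_instruments()` emulates the structure of the mineral tables:
true per-allele exposure effects drawn uniformly (defaults 0.02–0.08,
calcium-like), held fixed across the two samples (no sample overlap),
observed with noise at `se_exposure_level` (default 0.003, instrument F
roughly 45–700); outcome log-odds equal to causal effect × true exposure
beta, plus a direct (horizontally pleiotropic) effect for the invalid
fraction, plus noise at `se_outcome_level` (default 0.02). Direct effects
are drawn independently of instrument strength by default (InSIDE holds);
`inside = FALSE` couples them to exposure-beta deviations to demonstrate
Egger breakdown. Ground truth is attached to the returned set, and
`replicate_study()` summarizes bias, empirical SE, 95% coverage and
rejection rates over independently seeded replicates.

What the generator does *not* emulate: linkage disequilibrium between
instruments, allele-frequency-dependent precision, winner's-curse
selection of instruments, sample overlap, or non-linear exposure–outcome
relationships. Passing calibration tests therefore shows the estimators
are correct under the stated model, not that real-data violations of that
model are harmless.

Calibration scales, chosen to pin Monte-Carlo error well below the bands
being checked: 1,000 replicates for the type-I error of fixed-effect IVW
(binomial SE ≈ 0.007 against a ±0.02 band), 2,000 for 95% CI coverage
(SE ≈ 0.005), 500 for Egger-intercept recovery of an injected directional
mean of 0.02 (±0.005 band), and 200 for the median-vs-IVW robustness
ordering, run at `se_outcome_level = 0.001` so the valid and contaminated
ratio clusters separate — the regime the 50%-valid-weight consistency
result describes.

## Numerical and degenerate-input choices

* Wald ratio at `beta_exposure = 0` is a structured error, not `Inf`;
  `beta_outcome = 0` gives ratio 0 with the usual SE.
* All-identical ratios short-circuit the mode estimator (the mode is that
  value; no bandwidth is computable from zero spread) and give $Q = 0$,
  $p = 1$ exactly.
* The weighted-median interpolation clamps at the extreme ratios when one
  SNP carries more than half the weight.
* The mode bandwidth is floored at 1e−8 to keep the kernel proper when
  the ratio spread is tiny but non-zero.
* `f_statistic_from_summary()` is documented as an approximation from
  rounded printed statistics; F values reported by the source GWAS
  (computed upstream from unrounded data) are carried through unchanged
  and take precedence. On the printed 3-d.p. inputs the approximation
  can differ noticeably (e.g. 315 vs a reported 299).
* Replicate seeds are derived as `seed + i` and kept below 2³¹.

## Known limitations

With 6–7 instruments per exposure, MR-Egger and the mode estimator are
low-powered and bandwidth/convention-sensitive; the per-SD rescaling
treats the exposure SD as a known constant (0.5 and 0.1) with no
uncertainty; and the binary-outcome power formulas assume the rare-ish
outcome logistic approximation underlying their derivation. The package
reproduces a desk-scale analysis whose inputs are printed to 3 decimal
places — downstream quantities inherit that rounding, which is why the
reproduction tests carry explicit absolute tolerances rather than exact
equality beyond 2 decimal places.

## A worked pass

```{r worked, eval = FALSE}
calcium <- example_instruments("calcium")
mr_ivw(calcium)
mr_egger(calcium)$egger_intercept
run <- run_plan(default_plan())
run$results
detectable_or(394156, 6504, r_squared = 0.009, target_power = 0.8)
```
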