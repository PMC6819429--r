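# Synthetic two-sample summary statistics with known ground truth.
#
# The generator mimics the structure of the mineral instrument tables:
# per-SNP exposure betas with standard errors from one (exposure) sample and
# outcome log-odds with standard errors from a second, non-overlapping
# sample. Outcome effects are causal_effect * true exposure beta, plus a
# horizontal-pleiotropy term for the invalid fraction, plus sampling noise.

#' Configuration for the summary-statistic generator
#'
#' Defaults emulate a calcium-like instrument panel read against a large
#' case/non-case outcome GWAS: per-allele exposure effects of 0.02-0.08
#' exposure units estimated with SE 0.003 (instrument F roughly 45-700),
#' and outcome log-odds estimated with SE 0.02.
#'
#' @param n_snps Number of instruments.
#' @param causal_effect True causal log-odds per exposure unit.
#' @param exposure_beta_range Positive interval the true per-allele exposure
#'   effects are drawn from (uniform).
#' @param se_exposure_level Standard error of the observed exposure betas.
#' @param se_outcome_level Standard error of the observed outcome betas.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects)
#'   or `"directional"` (direct effects centred at `pleiotropy_mean`).
#' @param pleiotropy_mean Mean direct effect of invalid SNPs on the outcome
#'   (log-odds), used by the directional mode.
#' @param pleiotropy_sd SD of the direct effects.
#' @param invalid_fraction Expected fraction of SNPs carrying a direct
#'   (horizontal-pleiotropic) effect, in [0, 1].
#' @param inside If `TRUE` (default) direct effects are drawn independently
#'   of instrument strength (the InSIDE condition MR-Egger relies on); if
#'   `FALSE` they are made proportional to the exposure beta's deviation
#'   from its mean, breaking InSIDE to demonstrate Egger breakdown.
#' @param seed Integer seed; identical seeds give identical instrument sets.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_snps = 50,
                             causal_effect = 0,
                             exposure_beta_range = c(0.02, 0.08),
                             se_exposure_level = 0.003,
                             se_outcome_level = 0.02,
                             pleiotropy_mode = c("none", "balanced", "directional"),
                             pleiotropy_mean = 0,
                             pleiotropy_sd = 0.005,
                             invalid_fraction = 0,
                             inside = TRUE,
                             seed = 42) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_snps >= 1, length(exposure_beta_range) == 2)
  if (any(exposure_beta_range <= 0) ||
      exposure_beta_range[2] < exposure_beta_range[1]) {
    rlang::abort("exposure_beta_range must be a positive increasing interval",
                 class = "mr_validation_error")
  }
  if (se_exposure_level <= 0 || se_outcome_level <= 0) {
    rlang::abort("SE levels must be positive", class = "mr_validation_error")
  }
  if (invalid_fraction < 0 || invalid_fraction > 1) {
    rlang::abort("invalid_fraction must lie in [0, 1]",
                 class = "mr_validation_error")
  }
  if (pleiotropy_sd < 0) {
    rlang::abort("pleiotropy_sd must be non-negative",
                 class = "mr_validation_error")
  }
  structure(
    list(n_snps = as.integer(n_snps), causal_effect = causal_effect,
         exposure_beta_range = exposure_beta_range,
         se_exposure_level = se_exposure_level,
         se_outcome_level = se_outcome_level,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
         invalid_fraction = invalid_fraction, inside = inside,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Simulate a two-sample instrument set with recorded ground truth
#'
#' True per-allele exposure effects are drawn uniformly from the configured
#' range and held fixed across the two samples (no sample overlap). Observed
#' exposure betas add normal noise at `se_exposure_level`; outcome betas are
#' `causal_effect * true beta + direct effect + noise` at
#' `se_outcome_level`, where the direct effect is zero for valid SNPs and
#' normal(`pleiotropy_mean`, `pleiotropy_sd`) (mean forced to 0 under the
#' balanced mode) for the invalid fraction.
#'
#' @param cfg A [synthetic_config()].
#' @return An [instrument_set()]; `attr(, "truth")` records the causal
#'   effect, per-SNP validity, true exposure betas and direct effects.
#' @export
simulate_instruments <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  n <- cfg$n_snps
  with_preserved_seed(cfg$seed, {
    true_bx <- stats::runif(n, cfg$exposure_beta_range[1],
                            cfg$exposure_beta_range[2])
    bx <- true_bx + stats::rnorm(n, 0, cfg$se_exposure_level)
    invalid <- stats::runif(n) < cfg$invalid_fraction
    direct <- numeric(n)
    if (cfg$pleiotropy_mode != "none" && any(invalid)) {
      mu <- if (cfg$pleiotropy_mode == "directional") cfg$pleiotropy_mean else 0
      direct[invalid] <- stats::rnorm(sum(invalid), mu, cfg$pleiotropy_sd)
      if (!cfg$inside) {
        # couple direct effects to instrument strength (violates InSIDE)
        dev <- true_bx[invalid] - mean(true_bx)
        direct[invalid] <- direct[invalid] + mu * dev / stats::sd(true_bx)
      }
    }
    by <- cfg$causal_effect * true_bx + direct +
      stats::rnorm(n, 0, cfg$se_outcome_level)
    eaf <- stats::runif(n, 0.1, 0.9)
    snps <- tibble::tibble(
      rsid = sprintf("snp_%03d", seq_len(n)),
      chromosome = as.character(1 + (seq_len(n) - 1) %% 22),
      effect_allele = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      eaf = eaf,
      beta_exposure = bx,
      se_exposure = rep(cfg$se_exposure_level, n),
      p_exposure = pmax(2 * stats::pnorm(-abs(bx / cfg$se_exposure_level)),
                        .Machine$double.xmin),
      beta_outcome = by,
      se_outcome = rep(cfg$se_outcome_level, n),
      p_outcome = pmax(2 * stats::pnorm(-abs(by / cfg$se_outcome_level)),
                       .Machine$double.xmin)
    )
    set <- instrument_set(
      snps,
      exposure_spec("synthetic", sd_value = 1, sd_units = "exposure SD",
                    variance_explained = 0.01),
      label = sprintf("synthetic (seed %d)", cfg$seed)
    )
    attr(set, "truth") <- list(
      causal_effect = cfg$causal_effect,
      valid = !invalid,
      true_beta_exposure = true_bx,
      direct_effect = direct
    )
    set
  })
}

#' Monte-Carlo study of an estimator on synthetic instruments
#'
#' Runs [simulate_instruments()] plus an estimator over `n_replicates`
#' independently seeded replicates and summarizes bias, empirical SE, 95% CI
#' coverage of the true causal effect, and the rejection rate of the null at
#' `alpha`. Estimator failures are counted and reported, never fatal.
#'
#' @param cfg A [synthetic_config()]; its seed field is ignored in favour of
#'   `seed`.
#' @param estimator A method name (`"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"`) or a function mapping an instrument set to an
#'   `mr_result`.
#' @param n_replicates Number of replicates (>= 2).
#' @param seed Base seed; replicate `i` runs under `seed + i`.
#' @param alpha Nominal test level for the rejection rate.
#' @return An object of class `mr_replication`: list with `replicates`
#'   (one row per replicate: estimate, SE, CI coverage flag, rejection
#'   flag, error message if any) and `summary` (one row: n, failures, mean
#'   bias, empirical SE, mean model SE, coverage, rejection rate).
#' @export
replicate_study <- function(cfg, estimator, n_replicates, seed = cfg$seed,
                            alpha = 0.05) {
  stopifnot(inherits(cfg, "synthetic_config"), n_replicates >= 2)
  fn <- if (is.function(estimator)) {
    estimator
  } else {
    switch(match.arg(estimator,
                     c("ivw", "egger", "weighted_median", "weighted_mode")),
           ivw = mr_ivw,
           egger = mr_egger,
           weighted_median = function(s)
             mr_weighted_median(s, bootstrap_spec(200, seed)),
           weighted_mode = function(s)
             mr_weighted_mode(s, bootstrap = bootstrap_spec(200, seed)))
  }
  truth <- cfg$causal_effect
  rows <- lapply(seq_len(n_replicates), function(i) {
    cfg_i <- cfg
    cfg_i$seed <- as.integer((seed + i) %% .Machine$integer.max)
    set <- simulate_instruments(cfg_i)
    res <- tryCatch(fn(set), error = function(e) e)
    if (inherits(res, "error")) {
      return(tibble::tibble(replicate = i, seed = cfg_i$seed,
                            estimate = NA_real_, se = NA_real_,
                            covered = NA, rejected = NA,
                            error = conditionMessage(res)))
    }
    z <- stats::qnorm(1 - alpha / 2)
    tibble::tibble(
      replicate = i, seed = cfg_i$seed,
      estimate = res$beta_per_unit, se = res$se_per_unit,
      covered = abs(res$beta_per_unit - truth) <= 1.96 * res$se_per_unit,
      rejected = abs(res$beta_per_unit / res$se_per_unit) > z,
      error = NA_character_
    )
  })
  replicates <- dplyr::bind_rows(rows)
  ok <- replicates[is.na(replicates$error), , drop = FALSE]
  summary <- tibble::tibble(
    n_replicates = n_replicates,
    n_failed = sum(!is.na(replicates$error)),
    mean_bias = mean(ok$estimate) - truth,
    empirical_se = stats::sd(ok$estimate),
    mean_model_se = mean(ok$se),
    coverage = mean(ok$covered),
    rejection_rate = mean(ok$rejected),
    alpha = alpha
  )
  structure(list(replicates = replicates, summary = summary,
                 config = cfg, truth = truth),
            class = "mr_replication")
}

#' @export
print.mr_replication <- function(x, ...) {
  cat(sprintf("<mr_replication> %d replicates (%d failed), truth = %g\n",
              x$summary$n_replicates, x$summary$n_failed, x$truth))
  print(x$summary, ...)
  invisible(x)
}
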