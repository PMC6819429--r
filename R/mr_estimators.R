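# Causal estimators for two-sample MR on summary statistics.
#
# All estimators pool per-SNP Wald ratios with inverse-variance weights
# w_j = beta_exposure_j^2 / se_outcome_j^2 (the reciprocal of the first-order
# Wald-ratio variance), report the causal log-odds per exposure unit, and
# rescale to an odds ratio per one SD of the exposure.

#' Rescale a per-unit log-odds estimate to a per-SD odds ratio
#'
#' @param beta_per_unit Causal log-odds per exposure unit.
#' @param se_per_unit Its standard error.
#' @param sd_value Exposure standard deviation (same units as the betas'
#'   denominators).
#' @return List with `beta_per_sd`, `se_per_sd`, `or_per_sd`, `ci_low`,
#'   `ci_high` (95%, normal 1.96 multiplier) and the two-sided normal
#'   `p_value` (computed from `beta/se`, hence invariant to `sd_value`).
#' @export
scale_to_or <- function(beta_per_unit, se_per_unit, sd_value) {
  stopifnot(sd_value > 0, se_per_unit > 0)
  z <- beta_per_unit / se_per_unit
  list(
    beta_per_sd = beta_per_unit * sd_value,
    se_per_sd = se_per_unit * sd_value,
    or_per_sd = exp(beta_per_unit * sd_value),
    ci_low = exp((beta_per_unit - 1.96 * se_per_unit) * sd_value),
    ci_high = exp((beta_per_unit + 1.96 * se_per_unit) * sd_value),
    p_value = 2 * stats::pnorm(-abs(z))
  )
}

ivw_weights <- function(snps) snps$beta_exposure^2 / snps$se_outcome^2

per_snp_table <- function(set) {
  wr <- wald_ratio(set)
  sdv <- set$exposure$sd_value
  tibble::tibble(
    rsid = wr$rsid,
    ratio = wr$ratio,
    se = wr$se,
    or_per_sd = exp(wr$ratio * sdv),
    ci_low = exp((wr$ratio - 1.96 * wr$se) * sdv),
    ci_high = exp((wr$ratio + 1.96 * wr$se) * sdv),
    p_value = 2 * stats::pnorm(-abs(wr$ratio / wr$se))
  )
}

new_mr_result <- function(method, set, beta_per_unit, se_per_unit,
                          q = NULL, egger_intercept = NULL) {
  sc <- scale_to_or(beta_per_unit, se_per_unit, set$exposure$sd_value)
  structure(
    list(
      method = method,
      label = set$label,
      exposure = set$exposure,
      beta_per_unit = beta_per_unit,
      se_per_unit = se_per_unit,
      beta_per_sd = sc$beta_per_sd,
      se_per_sd = sc$se_per_sd,
      or_per_sd = sc$or_per_sd,
      ci_low = sc$ci_low,
      ci_high = sc$ci_high,
      p_value = sc$p_value,
      n_snps = n_snps(set),
      q_statistic = q$q %||% NULL,
      q_df = q$df %||% NULL,
      q_p = q$p %||% NULL,
      egger_intercept = egger_intercept,
      per_snp = per_snp_table(set)
    ),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s on %s (%d SNPs)\n", x$method, x$label, x$n_snps))
  cat(sprintf("  OR per SD: %.2f (95%% CI %.2f-%.2f), p = %.2g\n",
              x$or_per_sd, x$ci_low, x$ci_high, x$p_value))
  cat(sprintf("  log-odds per unit: %.4f (SE %.4f); per SD of %g %s: %.4f\n",
              x$beta_per_unit, x$se_per_unit, x$exposure$sd_value,
              x$exposure$sd_units, x$beta_per_sd))
  if (!is.null(x$q_statistic)) {
    cat(sprintf("  heterogeneity: Q = %.3f on %d df, p = %.2f\n",
                x$q_statistic, x$q_df, x$q_p))
  }
  if (!is.null(x$egger_intercept)) {
    ei <- x$egger_intercept
    cat(sprintf("  intercept: %.3f (95%% CI %.3f to %.3f), p = %.2f\n",
                ei$estimate, ei$ci_low, ei$ci_high, ei$p_value))
  }
  invisible(x)
}

require_snps <- function(set, n, what) {
  if (n_snps(set) < n) {
    rlang::abort(
      sprintf("%s requires at least %d instruments; '%s' has %d",
              what, n, set$label, n_snps(set)),
      class = "mr_insufficient_instruments_error"
    )
  }
}

#' Cochran's Q heterogeneity statistic across per-SNP causal estimates
#'
#' `Q = sum_j w_j (ratio_j - beta_ref)^2` with inverse-variance weights
#' `w_j = beta_exposure_j^2 / se_outcome_j^2`, referred to a chi-square
#' distribution on `n - 1` degrees of freedom.
#'
#' @param set An [instrument_set()] with at least 2 SNPs.
#' @param beta_ref Reference causal estimate (typically the IVW estimate).
#' @return List with `q`, `df`, `p`.
#' @export
cochran_q <- function(set, beta_ref) {
  require_snps(set, 2, "Cochran's Q")
  w <- ivw_weights(set$snps)
  r <- wald_ratio(set)$ratio
  q <- sum(w * (r - beta_ref)^2)
  df <- n_snps(set) - 1L
  list(q = q, df = df, p = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Inverse-variance weighted causal estimate
#'
#' Pools the per-SNP Wald ratios with weights
#' `w_j = beta_exposure_j^2 / se_outcome_j^2`:
#' `beta = sum(bx*by/sy^2) / sum(bx^2/sy^2)`, algebraically the weighted
#' least-squares slope of the outcome betas on the exposure betas through
#' the origin. The fixed-effect standard error is `1/sqrt(sum(w))`; under
#' `model = "multiplicative_random"` it is inflated by
#' `max(1, sqrt(Q/(n-1)))` (never deflated when the instruments are
#' under-dispersed).
#'
#' @param set An [instrument_set()]; every `beta_exposure` must be non-zero.
#' @param model `"fixed"` (default) or `"multiplicative_random"`.
#' @return An `mr_result` with the Q statistic attached.
#' @examples
#' mr_ivw(example_instruments("calcium"))
#' @export
mr_ivw <- function(set, model = c("fixed", "multiplicative_random")) {
  model <- match.arg(model)
  require_snps(set, 1, "IVW")
  snps <- set$snps
  if (any(snps$beta_exposure == 0)) {
    rlang::abort("IVW undefined: a beta_exposure is zero",
                 class = "mr_undefined_ratio_error")
  }
  w <- ivw_weights(snps)
  beta <- sum(snps$beta_exposure * snps$beta_outcome / snps$se_outcome^2) / sum(w)
  se <- 1 / sqrt(sum(w))
  q <- if (n_snps(set) >= 2) cochran_q(set, beta) else NULL
  if (model == "multiplicative_random") {
    if (is.null(q)) {
      message("single instrument: multiplicative_random falls back to fixed")
    } else {
      se <- se * max(1, sqrt(q$q / q$df))
    }
  }
  new_mr_result(paste0("ivw_", model), set, beta, se, q = q)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome betas on the exposure betas
#' with a free intercept and weights `1/se_outcome^2`, after re-orienting
#' every SNP so that `beta_exposure >= 0` (flipping the outcome beta
#' accordingly). The slope is the pleiotropy-adjusted causal estimate; the
#' intercept, reported with a normal 95% CI and two-sided p, is the test
#' for directional pleiotropy (its expectation is zero when horizontal
#' pleiotropic effects are balanced).
#'
#' The default `se = "floored"` standard errors divide the model-based WLS
#' standard errors by `min(1, sigma_hat)` — equivalently, the fixed-effect
#' standard errors inflated by `max(1, sqrt(Q'/(n-2)))` where `Q'` is the
#' residual heterogeneity about the Egger fit. This is the usual MR-Egger
#' convention: over-dispersion widens the intervals and under-dispersion is
#' never allowed to narrow them. `se = "plain"` reports the unmodified WLS
#' standard errors.
#'
#' @param set An [instrument_set()] with at least 3 SNPs.
#' @param se Standard-error convention, `"floored"` (default) or `"plain"`.
#' @return An `mr_result`; `$egger_intercept` holds the intercept estimate,
#'   SE, CI, p, and the residual dispersion `sigma` (`sqrt(Q'/(n-2))`).
#' @examples
#' mr_egger(example_instruments("calcium"))$egger_intercept$estimate
#' @export
mr_egger <- function(set, se = c("floored", "plain")) {
  se_convention <- match.arg(se)
  require_snps(set, 3, "MR-Egger")
  snps <- set$snps
  flip <- sign(snps$beta_exposure)
  if (any(flip == 0)) {
    rlang::abort("MR-Egger undefined: a beta_exposure is zero",
                 class = "mr_undefined_ratio_error")
  }
  bx <- snps$beta_exposure * flip
  by <- snps$beta_outcome * flip
  if (stats::sd(bx) == 0) {
    rlang::abort("MR-Egger degenerate: no variance in exposure betas",
                 class = "mr_degenerate_design_error")
  }
  w <- 1 / snps$se_outcome^2
  fit <- stats::lm(by ~ bx, weights = w)
  cf <- summary(fit)$coefficients
  sigma <- summary(fit)$sigma  # sqrt(Q' / (n - 2)) for unit-variance weights
  infl <- if (se_convention == "floored") 1 / min(1, sigma) else 1
  slope <- cf["bx", "Estimate"]
  slope_se <- cf["bx", "Std. Error"] * infl
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] * infl
  egger_intercept <- list(
    estimate = int,
    se = int_se,
    ci_low = int - 1.96 * int_se,
    ci_high = int + 1.96 * int_se,
    p_value = 2 * stats::pnorm(-abs(int / int_se)),
    sigma = sigma
  )
  new_mr_result("egger", set, slope, slope_se,
                egger_intercept = egger_intercept)
}

# Interpolated weighted median: sort values, normalize weights, place each
# observation at its cumulative-weight midpoint, interpolate at 0.5.
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  p <- cumsum(w) - w / 2
  stats::approx(p, x, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Bootstrap settings for the median and mode estimators
#'
#' @param n_boot Number of parametric-bootstrap replicates.
#' @param seed Integer seed; the bootstrap is fully reproducible.
#' @export
bootstrap_spec <- function(n_boot = 1000, seed = 42) {
  stopifnot(n_boot >= 2)
  list(n_boot = as.integer(n_boot), seed = as.integer(seed))
}

# Parametric bootstrap over the summary statistics: redraw each SNP's betas
# from normal(beta, se), recompute the point estimator, return the SD.
bootstrap_se <- function(set, point_fn, boot) {
  snps <- set$snps
  n <- nrow(snps)
  with_preserved_seed(boot$seed, {
    reps <- vapply(seq_len(boot$n_boot), function(i) {
      bx <- stats::rnorm(n, snps$beta_exposure, snps$se_exposure)
      by <- stats::rnorm(n, snps$beta_outcome, snps$se_outcome)
      point_fn(by / bx, bx^2 / snps$se_outcome^2)
    }, numeric(1))
    stats::sd(reps)
  })
}

#' Weighted-median causal estimate
#'
#' The interpolated 50% point of the Wald ratios ordered by value, under
#' normalized inverse-variance weights. Consistent when valid instruments
#' carry at least half of the total weight, so robust to up to 50% invalid
#' weight. The standard error comes from a parametric bootstrap: each SNP's
#' exposure and outcome betas are redrawn from normal(beta, SE), the
#' weighted median recomputed, and the SD over replicates taken.
#'
#' @param set An [instrument_set()] with at least 3 SNPs.
#' @param bootstrap A [bootstrap_spec()].
#' @return An `mr_result`.
#' @examples
#' mr_weighted_median(example_instruments("magnesium"))
#' @export
mr_weighted_median <- function(set, bootstrap = bootstrap_spec()) {
  require_snps(set, 3, "weighted median")
  r <- wald_ratio(set)$ratio
  w <- ivw_weights(set$snps)
  beta <- weighted_median(r, w)
  se <- bootstrap_se(set, function(r, w) weighted_median(r, w), bootstrap)
  new_mr_result("weighted_median", set, beta, se)
}

# Modified Silverman bandwidth for the mode estimator. The default follows
# the mode-based-estimation convention: 0.9 * min(sd, MAD) * n^(-1/5) on the
# unweighted ratios. "weighted_mad" derives the scale from the weighted MAD
# about the weighted median instead.
mode_bandwidth <- function(r, w, method = c("min_sd_mad", "weighted_mad")) {
  method <- match.arg(method)
  n <- length(r)
  s <- switch(method,
    min_sd_mad = 0.9 * min(stats::sd(r), stats::mad(r)) / n^(1 / 5),
    weighted_mad = {
      m <- weighted_median(r, w)
      0.9 * (1.4826 * weighted_median(abs(r - m), w)) / n^(1 / 5)
    }
  )
  max(s, 1e-8)
}

weighted_mode_point <- function(r, w, phi, bandwidth, grid_n = 512L) {
  h <- phi * mode_bandwidth(r, w, bandwidth)
  grid <- seq(min(r) - h, max(r) + h, length.out = grid_n)
  wn <- w / sum(w)
  dens <- vapply(grid, function(x) sum(wn * stats::dnorm(x, r, h)), numeric(1))
  peak <- which(dens == max(dens))
  if (length(peak) > 1) {
    # break exact ties toward the middle of the grid
    peak <- peak[which.min(abs(peak - (grid_n + 1) / 2))]
  }
  grid[peak]
}

#' Weighted mode-based causal estimate
#'
#' The mode of the kernel-smoothed (normal kernel) weighted distribution of
#' the Wald ratios, evaluated as the density argmax on a 512-point grid
#' spanning `[min(ratio) - h, max(ratio) + h]`. Consistent when the largest
#' group of instruments sharing the same causal estimate is valid (the
#' "plurality valid" condition), even if more than half of the weight is
#' invalid. Bandwidth `h = phi * s` with `s` the modified Silverman scale
#' `0.9 * min(sd, MAD) * n^(-1/5)` of the ratios; `phi` tunes smoothing.
#' The standard error comes from the same parametric bootstrap as
#' [mr_weighted_median()].
#'
#' @param set An [instrument_set()] with at least 3 SNPs.
#' @param phi Positive bandwidth multiplier (default 1).
#' @param bandwidth Scale convention: `"min_sd_mad"` (default) or
#'   `"weighted_mad"`.
#' @param bootstrap A [bootstrap_spec()].
#' @return An `mr_result`.
#' @examples
#' mr_weighted_mode(example_instruments("calcium"))
#' @export
mr_weighted_mode <- function(set, phi = 1,
                             bandwidth = c("min_sd_mad", "weighted_mad"),
                             bootstrap = bootstrap_spec()) {
  bandwidth <- match.arg(bandwidth)
  require_snps(set, 3, "weighted mode")
  if (!is.numeric(phi) || length(phi) != 1 || phi <= 0) {
    rlang::abort("phi must be a positive number", class = "mr_validation_error")
  }
  r <- wald_ratio(set)$ratio
  w <- ivw_weights(set$snps)
  if (max(r) - min(r) < .Machine$double.eps^0.5) {
    beta <- r[1]  # degenerate: all ratios identical, mode is that value
  } else {
    beta <- weighted_mode_point(r, w, phi, bandwidth)
  }
  se <- bootstrap_se(
    set,
    function(r, w) {
      if (max(r) - min(r) < .Machine$double.eps^0.5) r[1]
      else weighted_mode_point(r, w, phi, bandwidth)
    },
    bootstrap
  )
  new_mr_result("weighted_mode", set, beta, se)
}

# Run code under a given seed, restoring the caller's RNG state afterwards.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
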