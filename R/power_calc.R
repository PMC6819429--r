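# Statistical power arithmetic for MR with a binary outcome.
#
# Follows the published summary-statistic power derivation for
# case/non-case outcomes: the observable log-odds effect of the genetic
# score is attenuated by the case fraction K, its sampling variance scales
# as 1/(N * R2), and power is the two-sided normal tail beyond z_{1-a/2}
# shifted by the resulting non-centrality.

#' Assemble and validate a power query
#'
#' @param n_total Total sample size of the outcome GWAS.
#' @param n_cases Number of cases (must be below `n_total`).
#' @param r_squared Fraction of exposure variance explained by the
#'   instruments, in (0, 1).
#' @param odds_ratio True per-SD odds ratio to detect (positive).
#' @param alpha Two-sided significance level, in (0, 1). The default 0.05 is
#'   the cited calculator's convention; a Bonferroni-corrected level (e.g.
#'   0.01) can be supplied instead.
#' @return An object of class `power_query`.
#' @export
power_query <- function(n_total, n_cases, r_squared, odds_ratio,
                        alpha = 0.05) {
  stopifnot(n_total > 0, n_cases > 0)
  if (n_cases >= n_total) {
    rlang::abort("n_cases must be smaller than n_total",
                 class = "mr_validation_error")
  }
  if (r_squared <= 0 || r_squared >= 1) {
    rlang::abort("r_squared must lie in (0, 1)", class = "mr_validation_error")
  }
  if (odds_ratio <= 0) {
    rlang::abort("odds_ratio must be positive", class = "mr_validation_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    rlang::abort("alpha must lie in (0, 1)", class = "mr_validation_error")
  }
  structure(
    list(n_total = n_total, n_cases = n_cases, r_squared = r_squared,
         odds_ratio = odds_ratio, alpha = alpha),
    class = "power_query"
  )
}

#' Power of a binary-outcome MR analysis
#'
#' For case fraction `K = n_cases / n_total`, the attenuated log-odds
#' effect observable through the instruments is
#' `b = K * (OR / (1 + K * (OR - 1)) - 1)`, with sampling variance
#' `v = (K * (1 - K) - b^2) / (n_total * r_squared)`. The test statistic is
#' non-central chi-square on 1 df with non-centrality `b^2 / v`; power is
#' the probability it exceeds the two-sided significance threshold,
#' evaluated as `pnorm(sqrt(ncp) - z) + pnorm(-sqrt(ncp) - z)` with
#' `z = qnorm(1 - alpha/2)`.
#'
#' The attenuation is mildly asymmetric in `OR` versus `1/OR`, so power for
#' a risk OR and its protective reciprocal agree only approximately (they
#' coincide in the limit of small effects); [detectable_or()] therefore
#' solves the two directions separately.
#'
#' @param query A [power_query()]; alternatively supply the named fields
#'   directly.
#' @inheritParams power_query
#' @return Power as a fraction in (0, 1).
#' @examples
#' mr_power_binary(n_total = 394156, n_cases = 6504,
#'                 r_squared = 0.016, odds_ratio = 0.89)
#' @export
mr_power_binary <- function(query = NULL, n_total, n_cases, r_squared,
                            odds_ratio, alpha = 0.05) {
  if (is.null(query)) {
    query <- power_query(n_total, n_cases, r_squared, odds_ratio, alpha)
  }
  stopifnot(inherits(query, "power_query"))
  k <- query$n_cases / query$n_total
  or <- query$odds_ratio
  b <- k * (or / (1 + k * (or - 1)) - 1)
  v <- (k * (1 - k) - b^2) / (query$n_total * query$r_squared)
  if (v <= 0) return(1)  # attenuated effect saturates the outcome variance
  ncp <- sqrt(b^2 / v)
  z <- stats::qnorm(1 - query$alpha / 2)
  stats::pnorm(ncp - z) + stats::pnorm(-ncp - z)
}

#' Smallest odds ratio detectable at a target power
#'
#' Monotone root-solve of [mr_power_binary()] in the odds ratio, separately
#' for the risk direction (OR in (1, 10]) and the protective direction
#' (OR in [0.05, 1)). Because the binary-outcome attenuation is not exactly
#' symmetric in OR versus 1/OR, the protective bound is solved in its own
#' bracket rather than taken as the reciprocal of the risk bound.
#'
#' @inheritParams power_query
#' @param target_power Required power, in (0, 1).
#' @param tol Root-solve tolerance on the odds-ratio scale.
#' @return List with `or_risk` (>= 1), `or_protective` (<= 1), and the
#'   `target_power` both achieve to within the stated tolerance.
#' @examples
#' detectable_or(394156, 6504, r_squared = 0.009, target_power = 0.8)
#' @export
detectable_or <- function(n_total, n_cases, r_squared, alpha = 0.05,
                          target_power = 0.8, tol = 1e-9) {
  if (target_power <= 0 || target_power >= 1) {
    rlang::abort("target_power must lie in (0, 1)",
                 class = "mr_validation_error")
  }
  pw <- function(or) {
    mr_power_binary(power_query(n_total, n_cases, r_squared, or, alpha))
  }
  solve_branch <- function(lo, hi) {
    f <- function(or) pw(or) - target_power
    if (f(lo) >= 0) return(lo)  # target at or below the alpha floor
    if (f(hi) < 0) {
      rlang::abort(
        sprintf("target power %.3f unreachable for OR in [%g, %g]",
                target_power, lo, hi),
        class = "mr_no_solution_error"
      )
    }
    stats::uniroot(f, sort(c(lo, hi)), tol = tol)$root
  }
  list(
    or_risk = solve_branch(1 + 1e-9, 10),
    or_protective = solve_branch(1 - 1e-9, 0.05),
    target_power = target_power
  )
}
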