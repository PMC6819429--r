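test_that("IVW equals origin-constrained weighted least squares exactly", {
  for (set in list(calcium_set(), magnesium_set())) {
    fit <- mr_ivw(set)
    snps <- set$snps
    # independent normal-equations computation
    wls <- lm(beta_outcome ~ 0 + beta_exposure, data = snps,
              weights = 1 / snps$se_outcome^2)
    expect_equal(fit$beta_per_unit, unname(coef(wls)), tolerance = 1e-12)
    # fixed-effect SE is the unscaled normal-equations SE
    expect_equal(fit$se_per_unit,
                 1 / sqrt(sum(snps$beta_exposure^2 / snps$se_outcome^2)),
                 tolerance = 1e-12)
  }
})

test_that("single-instrument IVW is that SNP's Wald ratio", {
  one <- toy_set(bx = 0.05, by = -0.01, sy = 0.02)
  fit <- mr_ivw(one)
  expect_equal(fit$beta_per_unit, -0.01 / 0.05)
  expect_equal(fit$se_per_unit, 0.02 / 0.05)
  expect_message(rand <- mr_ivw(one, model = "multiplicative_random"),
                 "falls back to fixed")
  expect_equal(rand$se_per_unit, fit$se_per_unit)
})

test_that("IVW is invariant to re-orienting any SNP", {
  set.seed(3)
  mg <- magnesium_set()
  base <- mr_ivw(mg)$beta_per_unit
  for (i in seq_len(n_snps(mg))) {
    flipped <- mg
    flipped$snps$beta_exposure[i] <- -flipped$snps$beta_exposure[i]
    flipped$snps$beta_outcome[i] <- -flipped$snps$beta_outcome[i]
    expect_equal(mr_ivw(flipped)$beta_per_unit, base, tolerance = 1e-12)
  }
})

test_that("multiplicative random-effects model floors dispersion at 1", {
  mg <- mr_ivw(magnesium_set(), model = "multiplicative_random")
  mg_fixed <- mr_ivw(magnesium_set())
  # over-dispersed set: SE widens by sqrt(Q/df)
  expect_equal(mg$se_per_unit,
               mg_fixed$se_per_unit * sqrt(mg_fixed$q_statistic / mg_fixed$q_df),
               tolerance = 1e-12)
  expect_gt(mg$se_per_unit, mg_fixed$se_per_unit)
  # under-dispersed set: floored at the fixed-effect SE
  ca <- mr_ivw(calcium_set(), model = "multiplicative_random")
  ca_fixed <- mr_ivw(calcium_set())
  expect_lt(ca_fixed$q_statistic, ca_fixed$q_df)
  expect_equal(ca$se_per_unit, ca_fixed$se_per_unit)
})

test_that("Cochran's Q is zero iff all ratios agree, and tracks the IVW reference", {
  same <- toy_set(bx = c(0.02, 0.04, 0.05), by = c(0.02, 0.04, 0.05) * -0.3,
                  sy = c(0.01, 0.02, 0.015))
  q <- cochran_q(same, mr_ivw(same)$beta_per_unit)
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)
  expect_equal(q$df, 2)

  mixed <- toy_set(bx = c(0.02, 0.04, 0.05), by = c(0.01, -0.02, 0.004),
                   sy = c(0.01, 0.02, 0.015))
  expect_gt(cochran_q(mixed, mr_ivw(mixed)$beta_per_unit)$q, 0)

  expect_error(cochran_q(toy_set(0.05, 0.01, 0.02), 0),
               class = "mr_insufficient_instruments_error")
})

test_that("Q attached to IVW results matches a direct recomputation", {
  for (set in list(calcium_set(), magnesium_set())) {
    fit <- mr_ivw(set)
    w <- set$snps$beta_exposure^2 / set$snps$se_outcome^2
    r <- set$snps$beta_outcome / set$snps$beta_exposure
    expect_equal(fit$q_statistic, sum(w * (r - fit$beta_per_unit)^2))
    expect_equal(fit$q_df, n_snps(set) - 1L)
    expect_equal(fit$q_p,
                 pchisq(fit$q_statistic, fit$q_df, lower.tail = FALSE))
  }
})

test_that("Egger regression reproduces the closed-form weighted fit", {
  for (set in list(calcium_set(), magnesium_set())) {
    fit <- mr_egger(set, se = "plain")
    snps <- set$snps
    w <- 1 / snps$se_outcome^2
    x <- snps$beta_exposure
    y <- snps$beta_outcome
    xbar <- sum(w * x) / sum(w)
    ybar <- sum(w * y) / sum(w)
    slope <- sum(w * (x - xbar) * (y - ybar)) / sum(w * (x - xbar)^2)
    intercept <- ybar - slope * xbar
    expect_equal(fit$beta_per_unit, slope, tolerance = 1e-12)
    expect_equal(fit$egger_intercept$estimate, intercept, tolerance = 1e-12)

    # floored convention only ever widens the plain WLS intervals
    floored <- mr_egger(set)
    expect_gte(floored$egger_intercept$se, fit$egger_intercept$se - 1e-15)
    expect_equal(floored$egger_intercept$estimate,
                 fit$egger_intercept$estimate)
  }
})

test_that("Egger slope with the intercept forced to zero is the IVW estimate", {
  for (set in list(calcium_set(), magnesium_set())) {
    snps <- set$snps
    through_origin <- lm(beta_outcome ~ 0 + beta_exposure, data = snps,
                         weights = 1 / snps$se_outcome^2)
    expect_equal(unname(coef(through_origin)), mr_ivw(set)$beta_per_unit,
                 tolerance = 1e-12)
  }
})

test_that("exactly proportional betas give a zero Egger intercept", {
  prop <- toy_set(bx = c(0.02, 0.035, 0.05, 0.07),
                  by = c(0.02, 0.035, 0.05, 0.07) * -0.45,
                  sy = c(0.01, 0.02, 0.015, 0.03))
  fit <- mr_egger(prop)
  expect_equal(fit$egger_intercept$estimate, 0, tolerance = 1e-12)
  expect_equal(fit$beta_per_unit, -0.45, tolerance = 1e-12)
})

test_that("Egger re-orients exposure betas non-negative before fitting", {
  ca <- calcium_set()
  flipped <- ca
  flipped$snps$beta_exposure[2] <- -flipped$snps$beta_exposure[2]
  flipped$snps$beta_outcome[2] <- -flipped$snps$beta_outcome[2]
  expect_equal(mr_egger(flipped)$egger_intercept$estimate,
               mr_egger(ca)$egger_intercept$estimate, tolerance = 1e-12)

  expect_error(mr_egger(toy_set(c(0.05, 0.04), c(0, 0), c(0.01, 0.01))),
               class = "mr_insufficient_instruments_error")
  expect_error(
    mr_egger(toy_set(c(0.05, 0.05, 0.05), c(0.01, 0, 0.02),
                     c(0.01, 0.01, 0.01))),
    class = "mr_degenerate_design_error"
  )
})

test_that("weighted median interpolates the 50% point of the ratio distribution", {
  # equal weights reduce to the ordinary interpolated median
  eq <- toy_set(bx = rep(0.05, 5),
                by = 0.05 * c(-0.4, 0.1, -0.2, 0.3, -0.1),
                sy = rep(0.02, 5))
  fit <- mr_weighted_median(eq, bootstrap_spec(100, 1))
  expect_equal(fit$beta_per_unit, -0.1, tolerance = 1e-10)

  # all ratios equal c: estimate is exactly c regardless of weights
  const <- toy_set(bx = c(0.02, 0.04, 0.06), by = c(0.02, 0.04, 0.06) * 0.25,
                   sy = c(0.01, 0.03, 0.02))
  expect_equal(mr_weighted_median(const, bootstrap_spec(100, 1))$beta_per_unit,
               0.25, tolerance = 1e-10)

  expect_error(mr_weighted_median(toy_set(c(0.05, 0.04), c(0, 0), c(0.01, 0.01))),
               class = "mr_insufficient_instruments_error")
})

test_that("weighted median agrees with a brute-force cumulative-weight scan", {
  set.seed(19)
  for (n in 3:5) {
    for (rep in 1:40) {
      x <- rnorm(n)
      w <- runif(n, 0.1, 5)
      expect_equal(mrminerals:::weighted_median(x, w),
                   brute_force_weighted_median(x, w), tolerance = 1e-12)
    }
  }
})

test_that("weighted mode finds the dominant cluster of ratio estimates", {
  # all ratios equal c
  const <- toy_set(bx = c(0.02, 0.04, 0.06), by = c(0.02, 0.04, 0.06) * 0.25,
                   sy = c(0.01, 0.03, 0.02))
  expect_equal(mr_weighted_mode(const, bootstrap = bootstrap_spec(100, 1))$beta_per_unit,
               0.25, tolerance = 1e-10)

  # a 4-SNP majority cluster at -0.3 dominates two outliers
  cluster_by <- c(0.05, 0.06, 0.055, 0.045) * -0.3 +
    c(0.001, -0.001, 0.0005, -0.0005)
  clustered <- toy_set(
    bx = c(0.05, 0.06, 0.055, 0.045, 0.05, 0.06),
    by = c(cluster_by, 0.05 * 0.8, 0.06 * 0.9),
    sy = rep(0.02, 6)
  )
  fit <- mr_weighted_mode(clustered, bootstrap = bootstrap_spec(100, 1))
  expect_lt(abs(fit$beta_per_unit - (-0.3)), 0.1)

  expect_error(
    mr_weighted_mode(calcium_set(), phi = -1),
    class = "mr_validation_error"
  )
  expect_error(
    mr_weighted_mode(toy_set(c(0.05, 0.04), c(0, 0), c(0.01, 0.01))),
    class = "mr_insufficient_instruments_error"
  )
})

test_that("bootstrap standard errors are reproducible and positive", {
  ca <- calcium_set()
  a <- mr_weighted_median(ca, bootstrap_spec(200, 7))
  b <- mr_weighted_median(ca, bootstrap_spec(200, 7))
  expect_identical(a$se_per_unit, b$se_per_unit)
  expect_gt(a$se_per_unit, 0)
  c1 <- mr_weighted_median(ca, bootstrap_spec(200, 8))
  expect_false(identical(a$se_per_unit, c1$se_per_unit))
})

test_that("per-SD scaling maps log-odds to odds ratios and leaves p alone", {
  null <- scale_to_or(0, 0.3, 0.5)
  expect_equal(null$or_per_sd, 1)
  expect_equal(null$ci_low * null$ci_high, 1, tolerance = 1e-12)
  expect_equal(null$p_value, 1)

  # hand-computed from the pooled calcium IVW algebra
  sc <- scale_to_or(-0.2252, 0.2827, 0.5)
  expect_equal(round(sc$or_per_sd, 2), 0.89)
  expect_equal(round(sc$ci_low, 2), 0.68)
  expect_equal(round(sc$ci_high, 2), 1.18)

  # p-values are invariant to the SD used for scaling
  expect_equal(scale_to_or(-0.9, 0.4, 0.1)$p_value,
               scale_to_or(-0.9, 0.4, 2.5)$p_value)

  # magnesium IVW per-unit estimate scaled by its SD of 0.1
  mg <- mr_ivw(magnesium_set())
  direct <- scale_to_or(mg$beta_per_unit, mg$se_per_unit, 0.1)
  expect_equal(round(direct$or_per_sd, 2), 0.89)
  expect_equal(direct$or_per_sd, mg$or_per_sd)
})

test_that("mr_result invariants hold across methods and fixtures", {
  boot <- bootstrap_spec(200, 5)
  fits <- list(
    mr_ivw(calcium_set()),
    mr_ivw(magnesium_set(), model = "multiplicative_random"),
    mr_egger(calcium_set()),
    mr_weighted_median(magnesium_set(), boot),
    mr_weighted_mode(calcium_set(), bootstrap = boot)
  )
  for (fit in fits) {
    expect_lte(fit$ci_low, fit$or_per_sd)
    expect_lte(fit$or_per_sd, fit$ci_high)
    expect_equal(fit$or_per_sd, exp(fit$beta_per_sd))
    expect_true(fit$p_value > 0 && fit$p_value <= 1)
    if (!is.null(fit$q_df)) expect_equal(fit$q_df, fit$n_snps - 1L)
    expect_equal(nrow(fit$per_snp), fit$n_snps)
  }
})
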