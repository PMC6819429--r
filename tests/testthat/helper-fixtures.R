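# Hand-typed copies of the packaged instrument tables, kept independent of
# the TSV reading path so file I/O and the estimators can check each other.

calcium_df <- function() {
  tibble::tibble(
    rsid = c("rs1801725", "rs1570669", "rs1550532", "rs7481584",
             "rs780094", "rs7336933", "rs10491003"),
    effect_allele = c("T", "G", "C", "G", "T", "G", "T"),
    eaf = c(0.15, 0.34, 0.31, 0.70, 0.42, 0.85, 0.09),
    f_statistic = c(299, 37, 37, 37, 37, 31, 31),
    beta_exposure = c(0.071, 0.018, 0.018, 0.018, 0.017, 0.022, 0.027),
    se_exposure = c(0.004, 0.003, 0.003, 0.003, 0.003, 0.004, 0.005),
    p_exposure = c(8.9e-86, 9.1e-12, 8.2e-11, 1.2e-10, 1.3e-10, 9.1e-10, 4.8e-09),
    beta_outcome = c(-0.032, 0.014, 0.004, 0.003, 0.008, -0.013, -0.030),
    se_outcome = c(0.027, 0.018, 0.018, 0.018, 0.017, 0.024, 0.031),
    p_outcome = c(0.236, 0.457, 0.829, 0.888, 0.652, 0.594, 0.344)
  )
}

magnesium_df <- function() {
  tibble::tibble(
    rsid = c("rs4072037", "rs7965584", "rs3925584", "rs11144134",
             "rs13146355", "rs448378"),
    effect_allele = c("T", "A", "T", "C", "A", "A"),
    eaf = c(0.53, 0.71, 0.55, 0.08, 0.44, 0.53),
    f_statistic = c(136, 60, 60, 55, 45, 31),
    beta_exposure = c(0.010, 0.007, 0.006, 0.011, 0.005, 0.004),
    se_exposure = c(0.001, 0.001, 0.001, 0.001, 0.001, 0.001),
    p_exposure = c(2.1e-36, 1.1e-16, 5.2e-16, 8.2e-15, 6.3e-13, 1.3e-08),
    beta_outcome = c(0.006, -0.021, 0.009, -0.022, -0.052, 0.003),
    se_outcome = c(0.017, 0.020, 0.017, 0.032, 0.018, 0.017),
    p_outcome = c(0.744, 0.286, 0.607, 0.505, 0.003, 0.864)
  )
}

calcium_set <- function() {
  instrument_set(calcium_df(), exposure_spec("calcium"), "calcium")
}

magnesium_set <- function() {
  instrument_set(magnesium_df(), exposure_spec("magnesium"), "magnesium")
}

# Tiny synthetic set builder for degenerate / property cases.
toy_set <- function(bx, by, sy, sx = rep(0.001, length(bx)),
                    sd_value = 1) {
  instrument_set(
    tibble::tibble(
      rsid = sprintf("toy_%d", seq_along(bx)),
      effect_allele = rep("A", length(bx)),
      beta_exposure = bx, se_exposure = sx,
      beta_outcome = by, se_outcome = sy
    ),
    exposure_spec("toy", sd_value = sd_value, sd_units = "unit",
                  variance_explained = 0.01),
    "toy"
  )
}

# Independent cumulative-weight scan for the interpolated weighted median:
# walks the sorted ratios accumulating weight until the midpoint positions
# bracket 0.5, then interpolates between the bracketing pair explicitly.
brute_force_weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cum <- 0
  mid <- numeric(length(x))
  for (j in seq_along(x)) {
    mid[j] <- cum + w[j] / 2
    cum <- cum + w[j]
  }
  if (0.5 <= mid[1]) return(x[1])
  if (0.5 >= mid[length(x)]) return(x[length(x)])
  for (j in seq_len(length(x) - 1)) {
    if (mid[j] <= 0.5 && 0.5 <= mid[j + 1]) {
      frac <- (0.5 - mid[j]) / (mid[j + 1] - mid[j])
      return(x[j] + frac * (x[j + 1] - x[j]))
    }
  }
  stop("unreachable")
}
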