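# Domain types and I/O for two-sample MR summary statistics.
#
# An instrument set bundles per-SNP exposure and outcome associations
# (betas, SEs, p-values, alleles) with an exposure specification that
# carries the SD used to rescale per-unit log-odds to per-SD odds ratios.

REQUIRED_COLUMNS <- c(
  "rsid", "effect_allele",
  "beta_exposure", "se_exposure",
  "beta_outcome", "se_outcome"
)

OPTIONAL_COLUMNS <- c(
  "mineral", "chromosome", "nearby_gene", "other_allele", "eaf",
  "f_statistic", "p_exposure", "p_outcome", "proxy_of", "proxy_r2"
)

#' Describe an exposure and its per-SD scaling
#'
#' An exposure specification records the name of the exposure, the standard
#' deviation used to rescale per-unit causal log-odds onto the per-SD scale,
#' and the fraction of exposure variance explained by the instrument set
#' (the R-squared that enters power calculations).
#'
#' Built-in presets: `"calcium"` (SD 0.5 mg/dl, instruments explain 0.9% of
#' variance) and `"magnesium"` (SD 0.1, unit string stored as printed by the
#' source GWAS, instruments explain 1.6% of variance).
#'
#' @param name Exposure name. `"calcium"` and `"magnesium"` fill in the
#'   remaining fields from the built-in presets unless overridden.
#' @param sd_value Positive standard deviation of the exposure, in `sd_units`.
#' @param sd_units Unit string for `sd_value`.
#' @param variance_explained Fraction of exposure variance explained by the
#'   instruments, in (0, 1).
#' @return An object of class `exposure_spec`.
#' @examples
#' exposure_spec("calcium")
#' exposure_spec("urate", sd_value = 1.2, sd_units = "mg/dl",
#'               variance_explained = 0.03)
#' @export
exposure_spec <- function(name, sd_value = NULL, sd_units = NULL,
                          variance_explained = NULL) {
  presets <- list(
    calcium   = list(sd_value = 0.5, sd_units = "mg/dl",
                     variance_explained = 0.009),
    magnesium = list(sd_value = 0.1, sd_units = "mmol/dl",
                     variance_explained = 0.016)
  )
  if (name %in% names(presets)) {
    p <- presets[[name]]
    sd_value <- sd_value %||% p$sd_value
    sd_units <- sd_units %||% p$sd_units
    variance_explained <- variance_explained %||% p$variance_explained
  }
  if (is.null(sd_value) || is.null(sd_units) || is.null(variance_explained)) {
    rlang::abort(
      "sd_value, sd_units and variance_explained are required for exposures without a preset",
      class = "mr_validation_error"
    )
  }
  stopifnot(is.numeric(sd_value), length(sd_value) == 1L)
  if (sd_value <= 0) {
    rlang::abort("sd_value must be positive", class = "mr_validation_error")
  }
  if (variance_explained <= 0 || variance_explained >= 1) {
    rlang::abort("variance_explained must lie in (0, 1)",
                 class = "mr_validation_error")
  }
  structure(
    list(name = name, sd_value = sd_value, sd_units = sd_units,
         variance_explained = variance_explained),
    class = "exposure_spec"
  )
}

#' @export
print.exposure_spec <- function(x, ...) {
  cat(sprintf("<exposure_spec> %s: SD = %g %s, variance explained = %g%%\n",
              x$name, x$sd_value, x$sd_units, 100 * x$variance_explained))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_snp_table <- function(snps) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(snps))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0("missing required column(s): ", paste(missing_cols, collapse = ", ")),
      class = "mr_parse_error"
    )
  }
  if (nrow(snps) == 0) {
    rlang::abort("no instruments", class = "mr_validation_error")
  }
  bad_se <- snps$rsid[snps$se_exposure <= 0 | snps$se_outcome <= 0]
  if (length(bad_se) > 0) {
    rlang::abort(
      paste0("non-positive standard error for: ", paste(bad_se, collapse = ", ")),
      class = "mr_validation_error"
    )
  }
  if (anyDuplicated(snps$rsid)) {
    rlang::abort(
      paste0("duplicated rsid: ",
             paste(unique(snps$rsid[duplicated(snps$rsid)]), collapse = ", ")),
      class = "mr_validation_error"
    )
  }
  if ("eaf" %in% names(snps)) {
    bad <- snps$rsid[!is.na(snps$eaf) & (snps$eaf < 0 | snps$eaf > 1)]
    if (length(bad) > 0) {
      rlang::abort(paste0("eaf outside [0, 1] for: ", paste(bad, collapse = ", ")),
                   class = "mr_validation_error")
    }
  }
  for (pcol in c("p_exposure", "p_outcome")) {
    if (pcol %in% names(snps)) {
      bad <- snps$rsid[!is.na(snps[[pcol]]) &
                         (snps[[pcol]] <= 0 | snps[[pcol]] > 1)]
      if (length(bad) > 0) {
        rlang::abort(paste0(pcol, " outside (0, 1] for: ",
                            paste(bad, collapse = ", ")),
                     class = "mr_validation_error")
      }
    }
  }
  invisible(snps)
}

#' Bundle SNP associations into an instrument set
#'
#' @param snps A data frame with one row per SNP. Required columns:
#'   `rsid`, `effect_allele`, `beta_exposure`, `se_exposure`,
#'   `beta_outcome`, `se_outcome`. Recognised optional columns:
#'   `chromosome`, `nearby_gene`, `other_allele`, `eaf`, `f_statistic`,
#'   `p_exposure`, `p_outcome`, `proxy_of`, `proxy_r2`.
#' @param exposure An [exposure_spec()].
#' @param label Free-text label identifying the set (used in result tables).
#' @return An object of class `instrument_set`.
#' @export
instrument_set <- function(snps, exposure, label = exposure$name) {
  stopifnot(inherits(exposure, "exposure_spec"))
  snps <- tibble::as_tibble(snps)
  validate_snp_table(snps)
  structure(
    list(exposure = exposure, snps = snps, label = label),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> %s: %d SNP(s), exposure %s (SD %g %s)\n",
              x$label, nrow(x$snps), x$exposure$name,
              x$exposure$sd_value, x$exposure$sd_units))
  print(x$snps, ...)
  invisible(x)
}

#' Number of instruments in a set
#' @param set An [instrument_set()].
#' @export
n_snps <- function(set) nrow(set$snps)

#' Read an instrument table from TSV
#'
#' Reads a tab-separated table of per-SNP summary statistics (UTF-8, one
#' header row) into an [instrument_set()]. Input row order is preserved.
#'
#' @param path Path to a TSV file.
#' @param exposure An [exposure_spec()] giving the per-SD scaling.
#' @param label Label for the set; defaults to the exposure name.
#' @return An `instrument_set`.
#' @export
read_instrument_table <- function(path, exposure, label = exposure$name) {
  if (!file.exists(path)) {
    rlang::abort(paste0("file not found: ", path), class = "mr_parse_error")
  }
  snps <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  keep <- intersect(names(snps), c(REQUIRED_COLUMNS, OPTIONAL_COLUMNS))
  instrument_set(snps[, keep, drop = FALSE], exposure, label)
}

#' Write an instrument table to TSV
#'
#' Inverse of [read_instrument_table()]: numeric fields round-trip exactly
#' at their stored precision.
#'
#' @param set An [instrument_set()].
#' @param path Output path.
#' @export
write_instrument_table <- function(set, path) {
  readr::write_tsv(set$snps, path)
  invisible(path)
}

#' Load the packaged calcium / magnesium instrument tables
#'
#' The package ships the 13 SNP instruments for serum calcium (7 SNPs) and
#' serum magnesium (6 SNPs) together with their heart-failure associations,
#' transcribed from the source GWAS summary tables. The tables are
#' pre-harmonized: exposure and outcome betas refer to the same effect
#' allele, and no other allele is recorded.
#'
#' @param mineral `"calcium"` or `"magnesium"`.
#' @return An `instrument_set`.
#' @examples
#' example_instruments("calcium")
#' @export
example_instruments <- function(mineral = c("calcium", "magnesium")) {
  mineral <- match.arg(mineral)
  path <- system.file("extdata", paste0(mineral, "_hf.tsv"),
                      package = "mrminerals", mustWork = TRUE)
  read_instrument_table(path, exposure_spec(mineral))
}

# ---- per-SNP derived quantities ---------------------------------------------

#' Per-SNP Wald ratio causal estimate
#'
#' The Wald ratio is the SNP-outcome association divided by the SNP-exposure
#' association, with a first-order delta-method standard error
#' `se_outcome / |beta_exposure|` (the uncertainty of the exposure beta is
#' ignored, consistent with the inverse-variance weighting used to pool the
#' ratios).
#'
#' @param snp A one-row data frame, list, or [instrument_set()]; for a set,
#'   one ratio per SNP is returned.
#' @return A tibble with columns `rsid` (if available), `ratio`, `se`.
#' @export
wald_ratio <- function(snp) {
  if (inherits(snp, "instrument_set")) snp <- snp$snps
  snp <- tibble::as_tibble(as.list(snp)[c(
    intersect(c("rsid"), names(snp)),
    c("beta_exposure", "beta_outcome", "se_outcome")
  )])
  if (any(snp$beta_exposure == 0)) {
    rlang::abort("Wald ratio undefined: beta_exposure is zero",
                 class = "mr_undefined_ratio_error")
  }
  out <- tibble::tibble(
    ratio = snp$beta_outcome / snp$beta_exposure,
    se = snp$se_outcome / abs(snp$beta_exposure)
  )
  if ("rsid" %in% names(snp)) out <- tibble::add_column(out, rsid = snp$rsid, .before = 1)
  out
}

#' Approximate instrument F-statistic from summary statistics
#'
#' Returns `(beta_exposure / se_exposure)^2`, the square of the Wald z for
#' the SNP-exposure association. This is an approximation: F values reported
#' by a source GWAS are computed upstream from unrounded statistics and take
#' precedence when present (they are carried through unchanged in the
#' `f_statistic` column).
#'
#' @param beta_exposure Per-allele exposure effect(s), or an
#'   [instrument_set()].
#' @param se_exposure Standard error(s); ignored when a set is given.
#' @return Numeric vector of approximate F-statistics.
#' @export
f_statistic_from_summary <- function(beta_exposure, se_exposure) {
  if (inherits(beta_exposure, "instrument_set")) {
    snps <- beta_exposure$snps
    beta_exposure <- snps$beta_exposure
    se_exposure <- snps$se_exposure
  }
  stopifnot(all(se_exposure > 0))
  (beta_exposure / se_exposure)^2
}

# ---- allele harmonization ---------------------------------------------------

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(ea, oa) {
  !is.na(oa) & toupper(oa) == COMPLEMENT[toupper(ea)]
}

#' Harmonize an exposure/outcome record pair onto the exposure orientation
#'
#' Aligns a SNP's outcome association to the exposure's effect allele. If the
#' outcome effect allele equals the exposure's other allele, the outcome beta
#' sign is flipped (and the outcome EAF reflected). Palindromic SNPs (A/T or
#' C/G) with exposure EAF inside the ambiguity window cannot be oriented from
#' strand information and are flagged `ambiguous`; under `policy =
#' "strict-drop"` they are dropped (`NULL` returned with a message).
#'
#' Records without an `other_allele` are treated as pre-harmonized and pass
#' through unchanged, as for tables whose outcome lookups were already
#' performed on the exposure orientation.
#'
#' @param exposure_record,outcome_record One-row data frames or named lists
#'   with `rsid`, `effect_allele`, optional `other_allele` and `eaf`, and
#'   `beta`/`se`/`p` (or the `beta_exposure`/`beta_outcome` style names).
#' @param policy `"flag-keep"` (default) or `"strict-drop"` for ambiguous
#'   palindromic SNPs.
#' @param eaf_window Allele-frequency window within which a palindromic SNP
#'   is deemed ambiguous.
#' @return A one-row tibble in the combined SNP-association layout with a
#'   logical `ambiguous` column, or `NULL` for a dropped SNP.
#' @export
harmonize_pair <- function(exposure_record, outcome_record,
                           policy = c("flag-keep", "strict-drop"),
                           eaf_window = c(0.42, 0.58)) {
  policy <- match.arg(policy)
  ex <- as.list(exposure_record)
  ou <- as.list(outcome_record)
  pick <- function(rec, base, side) {
    rec[[base]] %||% rec[[paste0(base, "_", side)]]
  }
  if (!identical(ex$rsid, ou$rsid)) {
    rlang::abort("records refer to different rsids",
                 class = "mr_harmonization_error")
  }
  ex_ea <- toupper(ex$effect_allele)
  ex_oa <- ex$other_allele
  if (!is.null(ex_oa) && !is.na(ex_oa)) ex_oa <- toupper(ex_oa) else ex_oa <- NA_character_
  ou_ea <- toupper(ou$effect_allele)
  ou_oa <- ou$other_allele
  if (!is.null(ou_oa) && !is.na(ou_oa)) ou_oa <- toupper(ou_oa) else ou_oa <- NA_character_

  beta_y <- pick(ou, "beta", "outcome")
  se_y <- pick(ou, "se", "outcome")
  p_y <- pick(ou, "p", "outcome")
  eaf_x <- ex$eaf

  aligned <- ou_ea == ex_ea && (is.na(ou_oa) || is.na(ex_oa) || ou_oa == ex_oa)
  swapped <- !is.na(ex_oa) && ou_ea == ex_oa &&
    (is.na(ou_oa) || ou_oa == ex_ea)
  if (!aligned && !swapped) {
    # try the complementary strand before giving up
    comp <- function(a) if (is.na(a)) NA_character_ else unname(COMPLEMENT[a])
    aligned <- comp(ou_ea) == ex_ea &&
      (is.na(ou_oa) || is.na(ex_oa) || comp(ou_oa) == ex_oa)
    swapped <- !is.na(ex_oa) && comp(ou_ea) == ex_oa &&
      (is.na(ou_oa) || comp(ou_oa) == ex_ea)
  }
  if (!aligned && !swapped) {
    rlang::abort(
      paste0("allele sets incompatible for ", ex$rsid,
             " (exposure ", ex_ea, "/", ex_oa,
             ", outcome ", ou_ea, "/", ou_oa, ")"),
      class = "mr_harmonization_error"
    )
  }
  if (swapped) beta_y <- -beta_y

  ambiguous <- isTRUE(is_palindromic(ex_ea, ex_oa)) &&
    !is.null(eaf_x) && !is.na(eaf_x) &&
    eaf_x >= eaf_window[1] && eaf_x <= eaf_window[2]
  if (ambiguous && policy == "strict-drop") {
    message("dropping ", ex$rsid,
            ": palindromic SNP with ambiguous allele frequency (eaf = ",
            format(eaf_x), ")")
    return(NULL)
  }

  tibble::tibble(
    rsid = ex$rsid,
    effect_allele = ex_ea,
    other_allele = ex_oa,
    eaf = eaf_x %||% NA_real_,
    beta_exposure = pick(ex, "beta", "exposure"),
    se_exposure = pick(ex, "se", "exposure"),
    p_exposure = pick(ex, "p", "exposure") %||% NA_real_,
    beta_outcome = beta_y,
    se_outcome = se_y,
    p_outcome = p_y %||% NA_real_,
    ambiguous = ambiguous
  )
}

# ---- exclusion sets ---------------------------------------------------------

#' Define a named SNP exclusion set
#'
#' Exclusion sets carry the bookkeeping for pleiotropy sensitivity analyses:
#' which SNPs to drop, why, and whether the flagged pleiotropy is horizontal
#' (violates the MR assumptions, so the SNP is excluded) or vertical
#' (mediated downstream of the exposure, recorded but retained).
#'
#' @param name Short identifier.
#' @param rsids Character vector of SNPs to remove.
#' @param rationale Free-text reason.
#' @param pleiotropy_class `"horizontal"` or `"vertical"`.
#' @return An object of class `exclusion_set`.
#' @export
exclusion_set <- function(name, rsids, rationale = "",
                          pleiotropy_class = c("horizontal", "vertical")) {
  pleiotropy_class <- match.arg(pleiotropy_class)
  stopifnot(is.character(rsids))
  structure(
    list(name = name, rsids = rsids, rationale = rationale,
         pleiotropy_class = pleiotropy_class),
    class = "exclusion_set"
  )
}

#' Built-in pleiotropy exclusion sets for the mineral instruments
#'
#' Confounder-trait lookups flag four of the 13 mineral SNPs: rs780094
#' (GCKR; metabolic-syndrome traits), rs3925584 (DCDC5) and rs13146355
#' (SHROOM3; kidney function), and rs448378 (MDS1; blood pressure). The
#' blood-pressure association is classified as vertical pleiotropy —
#' magnesium lowers blood pressure, so the path is downstream of the
#' exposure — and rs448378 is therefore retained rather than excluded.
#' `shroom3` additionally isolates rs13146355, the one SNP individually
#' associated with heart failure, for the heterogeneity sensitivity re-run.
#'
#' @return Named list of [exclusion_set()] objects: `gckr`, `kidney`,
#'   `shroom3`, and the retained `mds1`.
#' @export
pleiotropy_exclusions <- function() {
  list(
    gckr = exclusion_set(
      "gckr", "rs780094",
      "associated with the metabolic syndrome and its components",
      "horizontal"
    ),
    kidney = exclusion_set(
      "kidney", c("rs3925584", "rs13146355"),
      "associated with kidney function",
      "horizontal"
    ),
    shroom3 = exclusion_set(
      "shroom3", "rs13146355",
      "individually associated with the outcome; drives heterogeneity",
      "horizontal"
    ),
    mds1 = exclusion_set(
      "mds1", "rs448378",
      "blood pressure association; vertical (mediated) pleiotropy, retained",
      "vertical"
    )
  )
}

#' Remove an exclusion set's SNPs from an instrument set
#'
#' Returns a new set without the named SNPs; the input is untouched and the
#' provenance of the exclusion is recorded in the new label.
#'
#' @param set An [instrument_set()].
#' @param exclusion An [exclusion_set()] (or character vector of rsids).
#' @return A new `instrument_set`.
#' @export
apply_exclusion <- function(set, exclusion) {
  if (is.character(exclusion)) {
    exclusion <- exclusion_set("ad hoc", exclusion)
  }
  stopifnot(inherits(set, "instrument_set"), inherits(exclusion, "exclusion_set"))
  missing_rs <- setdiff(exclusion$rsids, set$snps$rsid)
  if (length(missing_rs) > 0) {
    rlang::abort(
      paste0("rsid(s) not present in instrument set '", set$label, "': ",
             paste(missing_rs, collapse = ", ")),
      class = "mr_configuration_error"
    )
  }
  if (length(exclusion$rsids) == 0) return(set)
  kept <- set$snps[!set$snps$rsid %in% exclusion$rsids, , drop = FALSE]
  instrument_set(kept, set$exposure,
                 label = paste0(set$label, " minus ", exclusion$name))
}
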