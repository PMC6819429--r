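# Orchestration of the full analysis grid: every method applied to every
# instrument set, plus IVW re-runs under each pleiotropy sensitivity
# exclusion, with Bonferroni significance flags and serializable outputs.

MR_METHODS <- c("ivw", "egger", "weighted_median", "weighted_mode")

#' Define an analysis plan
#'
#' @param instrument_sets Named list of [instrument_set()] objects.
#' @param methods Subset of `"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"weighted_mode"`.
#' @param sensitivity_exclusions List of [exclusion_set()] objects. Each is
#'   applied (with an IVW re-run) to every instrument set that contains all
#'   of its rsids; exclusions whose pleiotropy class is `"vertical"` are
#'   recorded but not re-run, mirroring the treatment of mediated effects.
#' @param bonferroni_alpha Significance threshold applied as a fixed
#'   comparison `p < bonferroni_alpha` (default 0.01, i.e. 0.05 corrected
#'   for two exposures and two outcomes).
#' @param output_dir If non-`NULL`, [run_plan()] writes `results.tsv`,
#'   `results.json`, and per-set `forest_*.tsv` / `scatter_*.tsv` here.
#' @param seed Integer seed for the bootstrap standard errors.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(instrument_sets,
                          methods = MR_METHODS,
                          sensitivity_exclusions = list(),
                          bonferroni_alpha = 0.01,
                          output_dir = NULL,
                          seed = 42) {
  if (length(instrument_sets) == 0) {
    rlang::abort("at least one instrument set is required",
                 class = "mr_validation_error")
  }
  if (length(methods) == 0) {
    rlang::abort("at least one method is required",
                 class = "mr_validation_error")
  }
  methods <- match.arg(methods, MR_METHODS, several.ok = TRUE)
  stopifnot(all(vapply(instrument_sets, inherits, logical(1), "instrument_set")))
  if (is.null(names(instrument_sets))) {
    names(instrument_sets) <- vapply(instrument_sets, `[[`, character(1), "label")
  }
  structure(
    list(instrument_sets = instrument_sets, methods = methods,
         sensitivity_exclusions = sensitivity_exclusions,
         bonferroni_alpha = bonferroni_alpha,
         output_dir = output_dir, seed = as.integer(seed)),
    class = "analysis_plan"
  )
}

#' The packaged mineral / heart-failure analysis plan
#'
#' Both packaged instrument sets, all four estimators, and the three
#' horizontal-pleiotropy sensitivity exclusions (rs780094; rs3925584 +
#' rs13146355; rs13146355 alone), at the Bonferroni threshold p < 0.01.
#'
#' @inheritParams analysis_plan
#' @export
default_plan <- function(output_dir = NULL, seed = 42) {
  analysis_plan(
    instrument_sets = list(
      calcium = example_instruments("calcium"),
      magnesium = example_instruments("magnesium")
    ),
    methods = MR_METHODS,
    sensitivity_exclusions = pleiotropy_exclusions(),
    bonferroni_alpha = 0.01,
    output_dir = output_dir,
    seed = seed
  )
}

run_method <- function(set, method, boot) {
  switch(method,
         ivw = mr_ivw(set),
         egger = mr_egger(set),
         weighted_median = mr_weighted_median(set, boot),
         weighted_mode = mr_weighted_mode(set, bootstrap = boot))
}

result_row <- function(set_name, method, analysis, res, alpha) {
  tibble::tibble(
    set = set_name,
    method = method,
    analysis = analysis,
    n_snps = res$n_snps,
    beta_per_unit = res$beta_per_unit,
    se_per_unit = res$se_per_unit,
    or_per_sd = res$or_per_sd,
    ci_low = res$ci_low,
    ci_high = res$ci_high,
    p_value = res$p_value,
    significant = res$p_value < alpha,
    q_statistic = res$q_statistic %||% NA_real_,
    q_df = res$q_df %||% NA_integer_,
    q_p = res$q_p %||% NA_real_,
    egger_intercept = res$egger_intercept$estimate %||% NA_real_,
    egger_intercept_p = res$egger_intercept$p_value %||% NA_real_
  )
}

#' Run every (instrument set x method) cell of an analysis plan
#'
#' Computes each primary cell, then re-runs IVW on each instrument set with
#' each applicable horizontal-pleiotropy exclusion applied. Estimator
#' precondition failures (e.g. too few instruments) are recorded as skipped
#' cells with the reason, never raised. Given the same plan and seed, two
#' runs produce byte-identical outputs.
#'
#' @param plan An [analysis_plan()].
#' @return An object of class `mr_analysis`: `results` (one row per cell),
#'   `fits` (the underlying `mr_result` objects, keyed `set.method`),
#'   `skipped` (cells that could not run), and `log` (seed, package
#'   version, R version, timestamp-free config echo).
#' @examples
#' \donttest{run_plan(default_plan())}
#' @export
run_plan <- function(plan) {
  stopifnot(inherits(plan, "analysis_plan"))
  boot <- bootstrap_spec(1000, plan$seed)
  rows <- list()
  fits <- list()
  skipped <- list()
  for (set_name in names(plan$instrument_sets)) {
    set <- plan$instrument_sets[[set_name]]
    for (method in plan$methods) {
      key <- paste(set_name, method, sep = ".")
      res <- tryCatch(run_method(set, method, boot), error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[key]] <- tibble::tibble(
          set = set_name, method = method, analysis = "primary",
          reason = conditionMessage(res))
        next
      }
      fits[[key]] <- res
      rows[[key]] <- result_row(set_name, method, "primary", res,
                                plan$bonferroni_alpha)
    }
  }
  for (excl in plan$sensitivity_exclusions) {
    if (identical(excl$pleiotropy_class, "vertical")) next
    for (set_name in names(plan$instrument_sets)) {
      set <- plan$instrument_sets[[set_name]]
      if (!all(excl$rsids %in% set$snps$rsid)) next
      key <- paste(set_name, "ivw", excl$name, sep = ".")
      analysis <- paste0("sensitivity:", excl$name)
      res <- tryCatch(mr_ivw(apply_exclusion(set, excl)),
                      error = function(e) e)
      if (inherits(res, "error")) {
        skipped[[key]] <- tibble::tibble(
          set = set_name, method = "ivw", analysis = analysis,
          reason = conditionMessage(res))
        next
      }
      fits[[key]] <- res
      rows[[key]] <- result_row(set_name, "ivw", analysis, res,
                                plan$bonferroni_alpha)
    }
  }
  out <- structure(
    list(
      results = dplyr::bind_rows(rows),
      fits = fits,
      skipped = if (length(skipped)) dplyr::bind_rows(skipped)
                else tibble::tibble(),
      log = list(
        seed = plan$seed,
        bonferroni_alpha = plan$bonferroni_alpha,
        methods = plan$methods,
        instrument_sets = vapply(plan$instrument_sets, function(s)
          nrow(s$snps), integer(1)),
        package_version = as.character(utils::packageVersion("mrminerals")),
        r_version = paste(R.version$major, R.version$minor, sep = ".")
      )
    ),
    class = "mr_analysis"
  )
  if (!is.null(plan$output_dir)) write_analysis(out, plan)
  out
}

#' @export
print.mr_analysis <- function(x, ...) {
  cat(sprintf("<mr_analysis> %d result(s), %d skipped\n",
              nrow(x$results), nrow(x$skipped)))
  print(x$results, ...)
  invisible(x)
}

write_analysis <- function(run, plan) {
  dir.create(plan$output_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$results, file.path(plan$output_dir, "results.tsv"))
  jsonlite::write_json(
    list(results = run$results, log = run$log),
    file.path(plan$output_dir, "results.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  for (set_name in names(plan$instrument_sets)) {
    key <- paste(set_name, "ivw", sep = ".")
    if (is.null(run$fits[[key]])) next
    readr::write_tsv(forest_data(run$fits[[key]]),
                     file.path(plan$output_dir,
                               paste0("forest_", set_name, ".tsv")))
    readr::write_tsv(scatter_data(plan$instrument_sets[[set_name]],
                                  run$fits[[key]]),
                     file.path(plan$output_dir,
                               paste0("scatter_", set_name, ".tsv")))
  }
  invisible(run)
}

#' Forest-plot table: per-SNP odds ratios plus the overall estimate
#'
#' One row per SNP (the Wald-ratio OR per SD with its 95% CI, in input
#' order) followed by a terminal `"Overall"` row carrying the pooled
#' estimate of the supplied result.
#'
#' @param result An `mr_result` with per-SNP diagnostics.
#' @return A tibble with columns `rsid`, `or_per_sd`, `ci_low`, `ci_high`,
#'   `p_value`, `type` (`"snp"` / `"overall"`).
#' @export
forest_data <- function(result) {
  stopifnot(inherits(result, "mr_result"))
  per_snp <- result$per_snp
  dplyr::bind_rows(
    tibble::tibble(
      rsid = per_snp$rsid,
      or_per_sd = per_snp$or_per_sd,
      ci_low = per_snp$ci_low,
      ci_high = per_snp$ci_high,
      p_value = per_snp$p_value,
      type = "snp"
    ),
    tibble::tibble(
      rsid = "Overall",
      or_per_sd = result$or_per_sd,
      ci_low = result$ci_low,
      ci_high = result$ci_high,
      p_value = result$p_value,
      type = "overall"
    )
  )
}

#' Scatter table: per-SNP effects with the fitted causal line
#'
#' Per-SNP (exposure beta, outcome beta, outcome SE) points together with
#' the fitted line of the supplied result: slope = causal log-odds per
#' exposure unit, intercept 0 for IVW-type fits and the Egger intercept for
#' MR-Egger.
#'
#' @param set The [instrument_set()] the result was computed from.
#' @param result An `mr_result` providing a slope.
#' @return A tibble of points with `slope` and `intercept` columns repeated
#'   on every row (convenient for plotting layers).
#' @export
scatter_data <- function(set, result) {
  stopifnot(inherits(set, "instrument_set"), inherits(result, "mr_result"))
  if (nrow(set$snps) == 0) {
    rlang::abort("empty instrument set", class = "mr_validation_error")
  }
  tibble::tibble(
    rsid = set$snps$rsid,
    beta_exposure = set$snps$beta_exposure,
    beta_outcome = set$snps$beta_outcome,
    se_outcome = set$snps$se_outcome,
    slope = result$beta_per_unit,
    intercept = result$egger_intercept$estimate %||% 0,
    fitted = (result$egger_intercept$estimate %||% 0) +
      result$beta_per_unit * set$snps$beta_exposure
  )
}

#' Serialize an analysis run to a flat JSON document
#'
#' @param run An `mr_analysis` from [run_plan()].
#' @param path Output path.
#' @export
write_results_json <- function(run, path) {
  stopifnot(inherits(run, "mr_analysis"))
  jsonlite::write_json(list(results = run$results, log = run$log),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
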