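#' Configuration for the synthetic inpatient cohort generator
#'
#' Builds and validates the parameter set of [generate_cohort()].  Defaults
#' target the summary statistics of a large multi-hospital inpatient
#' point-of-care glucose cohort: a median of 12 (IQR 5-24) readings per
#' admission, inter-reading gaps with 5th/25th/50th/75th/95th percentiles of
#' 0.58/2.48/3.88/4.88/8.23 hours, per-admission mean glucose with median
#' 141 (IQR 117-179) mg/dL, and four glycemic-variability strata defined by
#' the trailing 24-hour coefficient of variation (CV).
#'
#' @param n_admissions number of admissions to generate.
#' @param seed integer RNG seed; identical configs and seeds give
#'   byte-identical cohorts.
#' @param reading_count_params list with `meanlog`, `sdlog`, `min`: reading
#'   counts are drawn lognormal, rounded, and floored at `min` (default 4,
#'   the admission inclusion threshold).
#' @param gap_mixture_params list with `weights`, `meanlog`, `sdlog`
#'   describing a two-component lognormal mixture of inter-reading gaps in
#'   hours.  The default was fitted by quantile matching to the five target
#'   percentiles above (fit residual < 1e-6 relative).
#' @param admission_mean_params list with `meanlog`, `sdlog` for the
#'   lognormal distribution of per-admission mean glucose (mg/dL).
#' @param stratum_weights length-4 numeric, proportions of admissions
#'   targeted at the low/medium/high/very-high variability strata; must sum
#'   to 1.  Default follows the observation-level stratum proportions of the
#'   emulated cohort (approximately 0.166/0.592/0.187/0.054).
#' @param ar_coefficient optional scalar in `[0, 1)`: lag-1 autocorrelation
#'   of the glucose process applied to every admission.  When `NULL`
#'   (default) the per-stratum values in `stratum_ar` are used instead.
#' @param stratum_ar length-4 numeric in `[0, 1)`: per-stratum lag-1
#'   autocorrelation (low, medium, high, very_high).  Erratic glycemia is
#'   less self-correlated, so the default decreases across strata.
#' @param cv_target_ranges 4x2 matrix of per-stratum target-CV draw ranges;
#'   kept inside the stratum bands because the realized trailing-24h CV is a
#'   noisy estimate of the target.
#' @param covariate_flags logical, emit per-observation model-B covariates
#'   (insulin units on board by class, steroid equivalents, GFR, NPO)?
#' @param insulin_effect mg/dL decrease per unit of rapid-acting insulin on
#'   board; 0 (default) generates covariates independent of glucose, giving
#'   a known null for the covariate-adjusted learner comparison.
#' @param glucose_range length-2 numeric, physical truncation bounds in
#'   mg/dL for generated glucose.
#'
#' @return an object of class `bg_cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_admissions = 10, seed = 1)
#' cohort <- generate_cohort(cfg)
cohort_config <- function(n_admissions = 1000L,
                          seed = 20150101L,
                          reading_count_params = list(meanlog = log(12),
                                                      sdlog = 1.163,
                                                      min = 4L),
                          gap_mixture_params = list(
                            weights = c(0.4492653, 0.5507347),
                            meanlog = c(0.7768694, 1.4497050),
                            sdlog   = c(1.0835570, 0.2189257)),
                          admission_mean_params = list(meanlog = log(141),
                                                       sdlog = 0.315),
                          stratum_weights = c(low = 0.16617,
                                              medium = 0.59203,
                                              high = 0.18741,
                                              very_high = 0.05439),
                          ar_coefficient = NULL,
                          stratum_ar = c(low = 0.83, medium = 0.72,
                                         high = 0.60, very_high = 0.45),
                          cv_target_ranges = rbind(low = c(0.08, 0.13),
                                                   medium = c(0.19, 0.26),
                                                   high = c(0.34, 0.41),
                                                   very_high = c(0.48, 0.60)),
                          covariate_flags = TRUE,
                          insulin_effect = 0,
                          glucose_range = c(40, 600)) {
  assert_scalar_number(n_admissions, "n_admissions", lower = 1,
                       integer = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)

  for (fld in c("meanlog", "sdlog"))
    assert_scalar_number(reading_count_params[[fld]] %||% NA,
                         paste0("reading_count_params$", fld))
  if (reading_count_params$sdlog <= 0)
    config_error("reading_count_params$sdlog", "scale must be > 0")
  reading_count_params$min <- as.integer(reading_count_params$min %||% 4L)
  if (reading_count_params$min < 4L)
    config_error("reading_count_params$min",
                 "inclusion requires at least 4 readings per admission")

  g <- gap_mixture_params
  if (length(g$weights) != length(g$meanlog) ||
      length(g$weights) != length(g$sdlog) || length(g$weights) < 1L)
    config_error("gap_mixture_params", "weights/meanlog/sdlog lengths differ")
  if (any(!is.finite(unlist(g))))
    config_error("gap_mixture_params", "parameters must be finite")
  if (any(g$weights < 0) || abs(sum(g$weights) - 1) > 1e-9)
    config_error("gap_mixture_params$weights",
                 "must be non-negative and sum to 1")
  if (any(g$sdlog <= 0))
    config_error("gap_mixture_params$sdlog", "scale must be > 0")

  assert_scalar_number(admission_mean_params$meanlog %||% NA,
                       "admission_mean_params$meanlog")
  assert_scalar_number(admission_mean_params$sdlog %||% NA,
                       "admission_mean_params$sdlog", lower = 0)

  if (length(stratum_weights) != 4L)
    config_error("stratum_weights", "must have length 4")
  if (any(stratum_weights < 0) || abs(sum(stratum_weights) - 1) > 1e-9)
    config_error("stratum_weights", "must be non-negative and sum to 1")
  names(stratum_weights) <- stratum_levels()

  if (!is.null(ar_coefficient)) {
    assert_scalar_number(ar_coefficient, "ar_coefficient")
    if (ar_coefficient < 0 || ar_coefficient >= 1)
      config_error("ar_coefficient", "must lie in [0, 1)")
  }
  if (length(stratum_ar) != 4L || any(stratum_ar < 0) || any(stratum_ar >= 1))
    config_error("stratum_ar", "must be length 4 with values in [0, 1)")
  names(stratum_ar) <- stratum_levels()

  cv_target_ranges <- as.matrix(cv_target_ranges)
  if (!all(dim(cv_target_ranges) == c(4L, 2L)) ||
      any(cv_target_ranges <= 0) ||
      any(cv_target_ranges[, 2] < cv_target_ranges[, 1]))
    config_error("cv_target_ranges", "must be a 4x2 matrix of positive lo<=hi")
  rownames(cv_target_ranges) <- stratum_levels()

  if (!is.logical(covariate_flags) || length(covariate_flags) != 1L)
    config_error("covariate_flags", "must be TRUE or FALSE")
  assert_scalar_number(insulin_effect, "insulin_effect", lower = 0)
  if (length(glucose_range) != 2L || glucose_range[1] < 10 ||
      glucose_range[2] > 1000 || glucose_range[1] >= glucose_range[2])
    config_error("glucose_range", "must be increasing within [10, 1000]")

  structure(list(n_admissions = as.integer(n_admissions),
                 seed = as.integer(seed),
                 reading_count_params = reading_count_params,
                 gap_mixture_params = g,
                 admission_mean_params = admission_mean_params,
                 stratum_weights = stratum_weights,
                 ar_coefficient = ar_coefficient,
                 stratum_ar = stratum_ar,
                 cv_target_ranges = cv_target_ranges,
                 covariate_flags = covariate_flags,
                 insulin_effect = insulin_effect,
                 glucose_range = glucose_range),
            class = "bg_cohort_config")
}

#' @export
print.bg_cohort_config <- function(x, ...) {
  cat("<bg_cohort_config>\n")
  cat("  n_admissions:", x$n_admissions, " seed:", x$seed, "\n")
  cat("  stratum weights:",
      paste(sprintf("%s=%.3f", names(x$stratum_weights), x$stratum_weights),
            collapse = " "), "\n")
  ar <- if (is.null(x$ar_coefficient))
    paste0("per-stratum (", paste(x$stratum_ar, collapse = "/"), ")")
  else x$ar_coefficient
  cat("  lag-1 autocorrelation:", ar, "\n")
  cat("  covariates:", x$covariate_flags,
      " insulin effect:", x$insulin_effect, "mg/dL per unit\n")
  invisible(x)
}
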