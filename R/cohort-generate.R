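#' Generate one synthetic admission
#'
#' Draws a single admission: demographics, a variability stratum, reading
#' times as cumulative sums of mixture-of-lognormal gaps, and a glucose
#' series following a stationary lag-1 autoregressive (AR(1)) process around
#' the admission mean, truncated to the configured physical range.  The
#' marginal standard deviation of the process is `target_cv * admission
#' mean`, so the stratum label controls dispersion; the lag-1
#' autocorrelation is `config$ar_coefficient` when set, otherwise the
#' per-stratum default.
#'
#' Timestamps are rounded to whole minutes (EHR resolution, minimum gap one
#' minute) and glucose to whole mg/dL (meter resolution).
#'
#' @param config a [cohort_config()].
#' @param admission_id identifier for the admission.
#' @param seed optional integer; when supplied, the RNG is seeded first so
#'   the admission is reproducible in isolation.  When `NULL` the current
#'   RNG stream is consumed (as [generate_cohort()] does).
#' @return an object of class `bg_admission`: a list with one-row
#'   `admission` metadata, an `observations` data.frame (admission_id,
#'   t_minutes, glucose, source) and, if `config$covariate_flags`, a
#'   `covariates` data.frame with one record per observation.
#' @export
generate_admission <- function(config, admission_id = "A000001",
                               seed = NULL) {
  stopifnot(inherits(config, "bg_cohort_config"))
  if (!is.null(seed)) set.seed(seed)

  stratum <- sample(stratum_levels(), 1L, prob = config$stratum_weights)
  rng <- config$cv_target_ranges[stratum, ]
  target_cv <- runif(1L, rng[1], rng[2])
  rho <- config$ar_coefficient %||% unname(config$stratum_ar[stratum])

  mu <- rlnorm(1L, config$admission_mean_params$meanlog,
               config$admission_mean_params$sdlog)
  rc <- config$reading_count_params
  n <- max(rc$min, as.integer(round(rlnorm(1L, rc$meanlog, rc$sdlog))))

  gaps_h <- draw_gap_mixture(n - 1L, config$gap_mixture_params)
  t_minutes <- cumsum(c(0, pmax(1, round(gaps_h * 60))))

  # The sample SD inside a trailing 24-h window underestimates the marginal
  # SD of an autocorrelated series; inflate sigma so the expected window CV
  # hits the target (see window_shrink_factor()).
  sigma <- target_cv * mu / window_shrink_factor(t_minutes, rho)
  innov <- rnorm(n, 0, sigma * sqrt(1 - rho^2))
  dev <- as.numeric(stats::filter(innov, rho, method = "recursive",
                                  init = rnorm(1L, 0, sigma)))
  glucose <- mu + dev
  source <- ifelse(runif(n) < 0.2, "serum", "POC")

  demo <- list(
    age = min(100, max(18, round(rnorm(1L, 64, 15)))),
    sex = sample(c("female", "male"), 1L, prob = c(0.4936, 0.5064)),
    race = sample(c("black", "other", "white"), 1L,
                  prob = c(0.3191, 0.1148, 0.5661)),
    diabetes_dx = sample(c("none", "T1D", "T2D", "other"), 1L,
                         prob = c(0.6358, 0.0285, 0.3250, 0.0106)))
  home_insulin <- runif(1L) < ifelse(demo$diabetes_dx %in% c("T1D", "T2D"),
                                     0.5, 0.05)
  home_antihyperglycemic <- runif(1L) <
    switch(demo$diabetes_dx, T2D = 0.7, T1D = 0.15, other = 0.3, 0.02)

  covariates <- NULL
  if (config$covariate_flags) {
    covariates <- draw_covariates(admission_id, t_minutes, demo, home_insulin)
    if (config$insulin_effect > 0)
      glucose <- glucose - config$insulin_effect * covariates$insulin_rapid
  }
  glucose <- round(pmin(config$glucose_range[2],
                        pmax(config$glucose_range[1], glucose)))

  admission <- data.frame(
    admission_id = admission_id,
    age = demo$age, sex = demo$sex, race = demo$race,
    diabetes_dx = demo$diabetes_dx,
    home_insulin = home_insulin,
    home_antihyperglycemic = home_antihyperglycemic,
    admit_clock_min = as.integer(floor(runif(1L, 0, 7 * 24 * 60))),
    stratum_target = stratum, target_cv = target_cv,
    ar_coefficient = rho,
    stringsAsFactors = FALSE)

  observations <- data.frame(admission_id = admission_id,
                             t_minutes = as.numeric(t_minutes),
                             glucose = glucose, source = source,
                             stringsAsFactors = FALSE)
  structure(list(admission = admission, observations = observations,
                 covariates = covariates),
            class = "bg_admission")
}

# Expected ratio of the trailing-24h-window sample SD to the marginal SD of
# a stationary AR(1) observed at the admission's reading times: for a window
# of n_w consecutive readings, E[s^2] = sigma^2 * (1 - 2/(n_w (n_w - 1)) *
# sum_{d=1}^{n_w-1} (n_w - d) rho^d).  Averaged over the admission's actual
# windows with at least 2 readings.
window_shrink_factor <- function(t_minutes, rho) {
  if (rho == 0) return(1)
  i <- seq_along(t_minutes)
  n_w <- i - findInterval(t_minutes - 24 * 60 - 1e-9, t_minutes)
  n_w <- n_w[n_w >= 2]
  if (!length(n_w)) n_w <- 2L
  shrink2 <- vapply(n_w, function(m) {
    d <- seq_len(m - 1)
    1 - 2 / (m * (m - 1)) * sum((m - d) * rho^d)
  }, 0)
  sqrt(max(mean(shrink2), 0.05))
}

draw_gap_mixture <- function(n, params) {
  if (n == 0L) return(numeric(0))
  comp <- sample.int(length(params$weights), n, replace = TRUE,
                     prob = params$weights)
  rlnorm(n, params$meanlog[comp], params$sdlog[comp])
}

# Model-B covariates; independent of the glucose process unless the
# insulin_effect hook is enabled by the caller.
draw_covariates <- function(admission_id, t_minutes, demo, home_insulin) {
  n <- length(t_minutes)
  gfr <- min(150, max(5, rlnorm(1L, log(75), 0.4)))
  on_steroids <- runif(1L) < 0.063
  diabetic <- demo$diabetes_dx %in% c("T1D", "T2D", "other")
  insulin_class <- function(p_any) {
    active <- runif(1L) < p_any
    if (!active) return(numeric(n))
    round(pmax(0, rnorm(n, mean = rlnorm(1L, log(6), 0.5), sd = 2)), 1)
  }
  p_base <- if (home_insulin || diabetic) 0.55 else 0.15
  data.frame(
    admission_id = admission_id,
    t_minutes = as.numeric(t_minutes),
    npo = runif(n) < 0.15,
    gfr = round(gfr, 1),
    hydrocortisone_equiv =
      if (on_steroids) round(pmax(0, rnorm(n, 50, 15)), 1) else numeric(n),
    insulin_basal = insulin_class(p_base),
    insulin_combination = insulin_class(0.03),
    insulin_concentrated = insulin_class(0.02),
    insulin_intermediate = insulin_class(0.05),
    insulin_rapid = insulin_class(if (diabetic) 0.5 else 0.2),
    insulin_regular = insulin_class(0.10),
    insulin_ultralong = insulin_class(0.05),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic inpatient glucose cohort
#'
#' Repeatedly draws admissions from a single seeded RNG stream, so a given
#' `(config, seed)` pair always yields a byte-identical cohort.
#'
#' @param config a [cohort_config()].
#' @return an object of class `bg_cohort`: list with `admissions` (one row
#'   per admission), `observations` (one row per reading, sorted by
#'   admission and time), `covariates` (or `NULL`) and the `config`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_admissions = 5, seed = 42))
#' nrow(cohort$admissions)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "bg_cohort_config"))
  set.seed(config$seed)
  ids <- sprintf("A%06d", seq_len(config$n_admissions))
  adms <- vector("list", config$n_admissions)
  for (i in seq_along(ids)) adms[[i]] <- generate_admission(config, ids[i])

  bind <- function(field) {
    data.table::setDF(data.table::rbindlist(lapply(adms, `[[`, field)))
  }
  cohort <- structure(list(
    admissions = bind("admission"),
    observations = bind("observations"),
    covariates = if (config$covariate_flags) bind("covariates") else NULL,
    config = config), class = "bg_cohort")
  rownames(cohort$admissions) <- NULL
  rownames(cohort$observations) <- NULL
  if (!is.null(cohort$covariates)) rownames(cohort$covariates) <- NULL
  cohort
}

#' @export
print.bg_cohort <- function(x, ...) {
  cat("<bg_cohort> ", nrow(x$admissions), " admissions, ",
      nrow(x$observations), " BG observations\n", sep = "")
  cat("  median readings/admission: ",
      stats::median(table(x$observations$admission_id)), "\n", sep = "")
  invisible(x)
}
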