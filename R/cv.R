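#' Configuration for the cross-validated learner comparison
#'
#' @param sample_size number of prediction rows sampled (without
#'   replacement) for the experiment; the emulated analysis used 10,000.
#' @param n_folds number of cross-validation folds (default 5).
#' @param seed integer seed governing sampling, fold assignment and every
#'   stochastic learner; fold indices are identical across learners and
#'   feature sets for a given seed.
#' @param learners character vector of registry names (see
#'   [learner_registry()]); `"rule_ensemble_optional"` may be listed and is
#'   recorded as an unavailable substitution.
#' @param feature_sets subset of `c("model_A", "model_B")`.
#' @param group_by_admission assign whole admissions to folds instead of
#'   rows, preventing within-admission leakage (not the default, which
#'   replicates row-level sampling of observations).
#' @return an object of class `bg_experiment_config`.
#' @export
experiment_config <- function(sample_size = 10000L,
                              n_folds = 5L,
                              seed = 1L,
                              learners = c("linear", "partial_least_squares",
                                           "k_nearest_neighbors",
                                           "random_forest"),
                              feature_sets = c("model_A", "model_B"),
                              group_by_admission = FALSE) {
  assert_scalar_number(sample_size, "sample_size", lower = 10,
                       integer = TRUE)
  assert_scalar_number(n_folds, "n_folds", lower = 2, integer = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  if (!length(learners)) config_error("learners", "must be non-empty")
  known <- c(names(learner_registry()), "rule_ensemble_optional")
  bad <- setdiff(learners, known)
  if (length(bad))
    config_error("learners", paste("unknown learner(s):",
                                   paste(bad, collapse = ", ")))
  feature_sets <- match.arg(feature_sets, c("model_A", "model_B"),
                            several.ok = TRUE)
  structure(list(sample_size = as.integer(sample_size),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 learners = learners, feature_sets = feature_sets,
                 group_by_admission = isTRUE(group_by_admission)),
            class = "bg_experiment_config")
}

#' Cross-validated comparison of regression learners
#'
#' Draws a seeded random sample of prediction rows, assigns folds once
#' (identically reused across learners and feature sets), trains each
#' learner on each training fold under each feature set, and scores the
#' held-out fold with the evaluation module's squared Pearson correlation,
#' RMSE and median absolute error.  95% confidence intervals are
#' `mean +/- t(0.975, folds - 1) * sd / sqrt(folds)` across folds.
#'
#' @param rows a `bg_prediction_rows` data.frame with at least
#'   `config$sample_size` rows.
#' @param config an [experiment_config()].
#' @return data.frame of class `bg_cv_results` with one row per learner x
#'   feature set (metric means and CI bounds), carrying attributes
#'   `per_fold` (per-fold metric table) and `metadata` (seed, folds,
#'   chosen hyperparameters, learner substitutions, degenerate-fold flags).
#' @export
run_cv_experiment <- function(rows, config = experiment_config()) {
  stopifnot(inherits(config, "bg_experiment_config"))
  if (nrow(rows) < config$sample_size)
    config_error("sample_size",
                 sprintf("only %d rows available for sample_size=%d",
                         nrow(rows), config$sample_size))

  substitutions <- character(0)
  learners <- config$learners
  if ("rule_ensemble_optional" %in% learners) {
    learners <- setdiff(learners, "rule_ensemble_optional")
    substitutions <- paste("rule_ensemble_optional (Cubist) has no faithful",
                           "implementation in this environment; experiment",
                           "run with the remaining learners")
    if (!length(learners))
      config_error("learners", "no available learner remains")
  }
  registry <- learner_registry()[learners]

  set.seed(config$seed)
  take <- sample.int(nrow(rows), config$sample_size)
  sampled <- as.data.frame(rows)[take, , drop = FALSE]
  if (config$group_by_admission) {
    adm <- unique(sampled$admission_id)
    adm_fold <- setNames(sample(rep(seq_len(config$n_folds),
                                    length.out = length(adm))), adm)
    fold <- unname(adm_fold[sampled$admission_id])
  } else {
    fold <- sample(rep(seq_len(config$n_folds),
                       length.out = config$sample_size))
  }
  y <- sampled$target_bg

  features <- lapply(setNames(config$feature_sets, config$feature_sets),
                     function(fs) make_feature_matrix(sampled, fs))

  per_fold <- list()
  for (fs in config$feature_sets) {
    X <- features[[fs]]
    for (ln in names(registry)) {
      for (f in seq_len(config$n_folds)) {
        test <- fold == f
        degenerate <- var(y[test]) == 0
        model <- registry[[ln]]$fit(X[!test, , drop = FALSE], y[!test])
        pred <- registry[[ln]]$predict(model, X[test, , drop = FALSE])
        r2 <- if (degenerate || var(pred) == 0) NA_real_
              else r_squared(pred, y[test])
        per_fold[[length(per_fold) + 1L]] <- data.frame(
          learner = ln, feature_set = fs, fold = f, n_test = sum(test),
          rmse = rmse(pred, y[test]), r2 = r2, mae = mae(pred, y[test]),
          hyper = model$hyper %||% "none", degenerate = degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  per_fold <- do.call(rbind, per_fold)

  tcrit <- qt(0.975, config$n_folds - 1)
  agg <- function(sub, metric) {
    v <- sub[[metric]]
    m <- mean(v, na.rm = TRUE)
    se <- sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v)))
    c(m, m - tcrit * se, m + tcrit * se)
  }
  cells <- unique(per_fold[, c("learner", "feature_set")])
  results <- do.call(rbind, lapply(seq_len(nrow(cells)), function(k) {
    sub <- per_fold[per_fold$learner == cells$learner[k] &
                      per_fold$feature_set == cells$feature_set[k], ]
    r <- c(agg(sub, "rmse"), agg(sub, "r2"), agg(sub, "mae"))
    data.frame(learner = cells$learner[k],
               feature_set = cells$feature_set[k],
               rmse_mean = r[1], rmse_lo = r[2], rmse_hi = r[3],
               r2_mean = r[4], r2_lo = r[5], r2_hi = r[6],
               mae_mean = r[7], mae_lo = r[8], mae_hi = r[9],
               stringsAsFactors = FALSE)
  }))
  rownames(results) <- NULL

  hyper <- unique(per_fold[, c("learner", "feature_set", "fold", "hyper")])
  structure(results,
            class = c("bg_cv_results", "data.frame"),
            per_fold = per_fold,
            metadata = list(seed = config$seed, n_folds = config$n_folds,
                            sample_size = config$sample_size,
                            group_by_admission = config$group_by_admission,
                            hyperparameters = hyper,
                            substitutions = substitutions,
                            degenerate_folds =
                              per_fold[per_fold$degenerate,
                                       c("learner", "feature_set", "fold")]))
}

#' @export
print.bg_cv_results <- function(x, ...) {
  cat("<bg_cv_results>\n")
  for (k in seq_len(nrow(x)))
    cat(sprintf(
      "  %-22s %-8s RMSE %5.1f (%5.1f-%5.1f)  R2 %.3f (%.3f-%.3f)  MAE %5.1f\n",
      x$learner[k], x$feature_set[k], x$rmse_mean[k], x$rmse_lo[k],
      x$rmse_hi[k], x$r2_mean[k], x$r2_lo[k], x$r2_hi[k], x$mae_mean[k]))
  subs <- attr(x, "metadata")$substitutions
  if (length(subs)) cat("  note:", subs, "\n")
  invisible(x)
}

#' Compare learner results with single-predictor baselines
#'
#' Lays each learner's cross-validated squared correlation alongside the
#' plain correlation of each individual time-series predictor on the same
#' population, with an indicator of whether the baseline falls inside the
#' learner's 95% CI (`within`), below it (`below`, the learner is
#' significantly better) or above it (`above`).
#'
#' @param cv_results a `bg_cv_results` from [run_cv_experiment()].
#' @param baseline_summaries data.frame with `predictor_label` and `r2`
#'   columns, e.g. the `population_label == "all"` slice of
#'   [evaluate_grid()]'s correlation table.
#' @return data.frame with one row per learner x feature set x baseline.
#' @export
compare_models <- function(cv_results, baseline_summaries) {
  if (nrow(cv_results) == 0L || nrow(baseline_summaries) == 0L)
    return(data.frame(learner = character(0), feature_set = character(0),
                      learner_r2 = numeric(0), predictor_label = character(0),
                      predictor_r2 = numeric(0), ci_overlap = character(0)))
  out <- merge(
    data.frame(learner = cv_results$learner,
               feature_set = cv_results$feature_set,
               learner_r2 = cv_results$r2_mean,
               r2_lo = cv_results$r2_lo, r2_hi = cv_results$r2_hi),
    data.frame(predictor_label = baseline_summaries$predictor_label,
               predictor_r2 = baseline_summaries$r2),
    by = NULL)
  out$ci_overlap <- ifelse(out$predictor_r2 < out$r2_lo, "below",
                           ifelse(out$predictor_r2 > out$r2_hi,
                                  "above", "within"))
  out[order(out$learner, out$feature_set, -out$predictor_r2), ]
}
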