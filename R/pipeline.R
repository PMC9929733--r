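#' Default pipeline configuration
#'
#' A single hierarchical configuration drives every pipeline stage.  It has
#' three blocks: `cohort` (arguments of [cohort_config()]), `predictors`
#' (arguments of [predictor_config()]) and `experiment` (arguments of
#' [experiment_config()]); a top-level `seed` feeds any block that does not
#' set its own.  Configurations are stored as JSON.
#'
#' @param config `NULL`, a named list, or the path of a JSON file.
#' @return validated nested list of class `bg_pipeline_config`.
#' @export
pipeline_config <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config))
      config_error("config", paste("file not found:", config))
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- config %||% list()
  known <- c("seed", "cohort", "predictors", "experiment")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    config_error(unknown[1], "unknown configuration key")
  if (is.null(config$seed))
    config_error("seed", "missing required configuration key")
  assert_scalar_number(config$seed, "seed", integer = TRUE)

  cohort <- config$cohort %||% list()
  if (is.null(cohort$n_admissions))
    config_error("cohort$n_admissions", "missing required configuration key")
  if (is.null(cohort$seed)) cohort$seed <- config$seed
  experiment <- config$experiment %||% list()
  if (is.null(experiment$seed)) experiment$seed <- config$seed + 1L

  structure(list(seed = as.integer(config$seed),
                 cohort = do.call(cohort_config, cohort),
                 predictors = do.call(predictor_config,
                                      config$predictors %||% list()),
                 experiment = do.call(experiment_config, experiment)),
            class = "bg_pipeline_config")
}

.pipeline_stages <- c("simulate", "preprocess", "featurize", "evaluate",
                      "ml-compare", "report")

#' Run the end-to-end analysis pipeline
#'
#' Executes, in order, the requested subset of: `simulate` (synthetic
#' cohort CSVs), `preprocess` (exclusion-flagged observations, prediction
#' pairs, count report), `featurize` (prediction-row table with all
#' predictors, CV and stratum), `evaluate` (correlation and Clarke Error
#' Grid tables), `ml-compare` (cross-validated learner table) and `report`
#' (human-readable summary with figures).  Stages not requested are loaded
#' from the prior outputs in `out_dir`, so any stage can be resumed.  A
#' manifest with the config snapshot, seeds, per-stage row counts, package
#' version and timestamps is written alongside the outputs.
#'
#' @param config a [pipeline_config()], a named list, or a JSON file path.
#' @param out_dir output directory (created if needed).
#' @param stages character subset of the stage names, in any order.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config, out_dir, stages = .pipeline_stages) {
  cfg <- if (inherits(config, "bg_pipeline_config")) config
         else pipeline_config(config)
  bad <- setdiff(stages, .pipeline_stages)
  if (length(bad))
    config_error("stages", paste("unknown stage:", bad[1]))
  stages <- .pipeline_stages[.pipeline_stages %in% stages]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  manifest <- list(
    package = "nextbg",
    version = as.character(utils::packageVersion("nextbg")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = cfg$seed,
    config = config_snapshot(cfg),
    stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    if (!name %in% stages) return(invisible(NULL))
    message("[nextbg] stage ", name, " ...")
    counts <- tryCatch(fun(), error = function(e)
      bg_error(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
               "bg_stage_error"))
    manifest$stages[[name]] <<- counts
  }

  run_stage("simulate", function() {
    cohort <- generate_cohort(cfg$cohort)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    state$cohort <- cohort
    list(n_admissions = nrow(cohort$admissions),
         n_observations = nrow(cohort$observations))
  })

  run_stage("preprocess", function() {
    cohort <- state$cohort %||% read_cohort(file.path(out_dir, "cohort"))
    pre <- preprocess_cohort(cohort)
    data.table::fwrite(pre$observations,
                       file.path(out_dir, "observations_clean.csv"))
    data.table::fwrite(pre$pairs,
                       file.path(out_dir, "prediction_pairs.csv"))
    jsonlite::write_json(unclass(pre$report),
                         file.path(out_dir, "preprocess_report.json"),
                         auto_unbox = TRUE)
    state$pre <- pre
    unclass(pre$report)
  })

  run_stage("featurize", function() {
    pre <- state$pre %||% load_preprocessed(out_dir)
    rows <- build_prediction_rows(pre, cfg$predictors)
    data.table::fwrite(rows, file.path(out_dir, "prediction_rows.csv"))
    state$rows <- rows
    list(n_rows = nrow(rows),
         n_predictors = length(cfg$predictors$labels))
  })

  run_stage("evaluate", function() {
    rows <- state$rows %||% load_prediction_rows(out_dir)
    ev <- evaluate_grid(rows)
    data.table::fwrite(ev$correlation,
                       file.path(out_dir, "table2_correlation.csv"))
    data.table::fwrite(ev$clarke, file.path(out_dir, "table3_clarke.csv"))
    allr <- ev$correlation[ev$correlation$population_label == "all", ]
    best <- allr[which.max(allr$r2), ]
    jsonlite::write_json(
      list(n_rows = nrow(rows),
           best_predictor = best$predictor_label,
           best_r2 = best$r2,
           sample_and_hold_r2 = allr$r2[allr$predictor_label == "index_bg"]),
      file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
    state$eval <- ev
    list(n_correlation_cells = nrow(ev$correlation),
         n_clarke_rows = nrow(ev$clarke))
  })

  run_stage("ml-compare", function() {
    rows <- state$rows %||% load_prediction_rows(out_dir)
    ecfg <- cfg$experiment
    if (ecfg$sample_size > nrow(rows)) {
      ecfg$sample_size <- nrow(rows)   # clamp, recorded in manifest
    }
    cv <- run_cv_experiment(rows, ecfg)
    data.table::fwrite(as.data.frame(cv),
                       file.path(out_dir, "table4_cv.csv"))
    md <- attr(cv, "metadata")
    md$hyperparameters <- NULL
    jsonlite::write_json(md, file.path(out_dir, "ml_metadata.json"),
                         auto_unbox = TRUE)
    state$cv <- cv
    list(sample_size = ecfg$sample_size,
         n_learners = length(unique(cv$learner)))
  })

  run_stage("report", function() {
    render_report(out_dir)
    list(report = "report.md")
  })

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

config_snapshot <- function(cfg) {
  strip <- function(x) {
    x <- unclass(x)
    x$labels <- NULL
    lapply(x, function(v) if (is.matrix(v))
      apply(v, 1, function(r) as.list(setNames(r, c("lo", "hi"))),
            simplify = FALSE) else v)
  }
  list(seed = cfg$seed, cohort = strip(cfg$cohort),
       predictors = strip(cfg$predictors),
       experiment = strip(cfg$experiment))
}

load_preprocessed <- function(out_dir) {
  obs_f <- file.path(out_dir, "observations_clean.csv")
  pairs_f <- file.path(out_dir, "prediction_pairs.csv")
  if (!file.exists(obs_f) || !file.exists(pairs_f))
    bg_error("preprocess outputs not found; run the preprocess stage first",
             "bg_stage_error")
  obs <- data.table::setDF(data.table::fread(obs_f, colClasses = list(
    character = c("admission_id", "exclusion"))))
  pairs <- data.table::setDF(data.table::fread(pairs_f, colClasses = list(
    character = "admission_id")))
  cohort_dir <- file.path(out_dir, "cohort")
  admissions <- covariates <- NULL
  if (file.exists(file.path(cohort_dir, "admissions.csv"))) {
    cohort <- read_cohort(cohort_dir)
    admissions <- cohort$admissions
    covariates <- cohort$covariates
  }
  report <- if (file.exists(file.path(out_dir, "preprocess_report.json")))
    jsonlite::read_json(file.path(out_dir, "preprocess_report.json"),
                        simplifyVector = TRUE) else NULL
  structure(list(observations = obs, pairs = pairs, report = report,
                 admissions = admissions, covariates = covariates),
            class = "bg_preprocessed")
}

load_prediction_rows <- function(out_dir) {
  f <- file.path(out_dir, "prediction_rows.csv")
  if (!file.exists(f))
    bg_error("prediction_rows.csv not found; run the featurize stage first",
             "bg_stage_error")
  rows <- data.table::setDF(data.table::fread(f, colClasses = list(
    character = "admission_id")))
  for (fld in intersect(c("home_insulin", "home_antihyperglycemic", "npo"),
                        names(rows)))
    rows[[fld]] <- as.logical(rows[[fld]])
  class(rows) <- c("bg_prediction_rows", "data.frame")
  rows
}
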