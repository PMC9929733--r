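.bg_origin <- as.POSIXct("2015-01-01 00:00:00", tz = "UTC")

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` serializes a cohort to a directory of CSV files:
#' `observations.csv` (admission_id, datetime in ISO 8601, glucose_mgdl,
#' source), `admissions.csv` (admission-level metadata, including the
#' wall-clock admission start used to reconstruct `t_minutes`), and
#' `covariates.csv` when present.  `read_cohort()` reverses the mapping;
#' the round trip reproduces every field and ordering exactly.
#'
#' `read_cohort()` also accepts an observations file with a `t_minutes`
#' column instead of `datetime` (times relative to admission start).
#'
#' @param cohort a `bg_cohort`.
#' @param path directory to write to / read from (created if missing).
#' @return `write_cohort()` returns `path` invisibly; `read_cohort()`
#'   returns a `bg_cohort` (with a `NULL` config).
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "bg_cohort"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  obs <- cohort$observations
  admit <- cohort$admissions$admit_clock_min[
    match(obs$admission_id, cohort$admissions$admission_id)]
  out <- data.frame(
    admission_id = obs$admission_id,
    datetime = format(.bg_origin + (admit + obs$t_minutes) * 60,
                      "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    glucose_mgdl = obs$glucose,
    source = obs$source, stringsAsFactors = FALSE)
  data.table::fwrite(out, file.path(path, "observations.csv"))
  data.table::fwrite(cohort$admissions, file.path(path, "admissions.csv"))
  if (!is.null(cohort$covariates))
    data.table::fwrite(cohort$covariates, file.path(path, "covariates.csv"))
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  obs_file <- file.path(path, "observations.csv")
  adm_file <- file.path(path, "admissions.csv")
  if (!file.exists(obs_file))
    validation_error(sprintf("observations file not found: %s", obs_file))
  obs <- data.table::setDF(data.table::fread(obs_file,
                                             colClasses = list(
                                               character = "admission_id")))
  admissions <- if (file.exists(adm_file))
    data.table::setDF(data.table::fread(adm_file, colClasses = list(
      character = "admission_id"))) else NULL

  if (!"admission_id" %in% names(obs))
    validation_error("observations file lacks an admission_id column")
  gl_col <- intersect(c("glucose_mgdl", "glucose"), names(obs))[1]
  if (is.na(gl_col))
    validation_error("observations file lacks a glucose_mgdl column")

  if ("t_minutes" %in% names(obs)) {
    t_minutes <- as.numeric(obs$t_minutes)
  } else if ("datetime" %in% names(obs)) {
    dt <- as.POSIXct(obs$datetime, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
    bad <- which(is.na(dt))
    if (length(bad))
      validation_error(sprintf("row %d: unparseable datetime '%s'",
                               bad[1], obs$datetime[bad[1]]))
    abs_min <- as.numeric(difftime(dt, .bg_origin, units = "mins"))
    admit <- if (!is.null(admissions) &&
                 "admit_clock_min" %in% names(admissions)) {
      admissions$admit_clock_min[match(obs$admission_id,
                                       admissions$admission_id)]
    } else {
      stats::ave(abs_min, obs$admission_id, FUN = min)
    }
    t_minutes <- abs_min - admit
  } else {
    validation_error("observations file needs a datetime or t_minutes column")
  }

  glucose <- as.numeric(obs[[gl_col]])
  bad <- which(!is.finite(glucose) | glucose <= 0)
  if (length(bad))
    validation_error(sprintf(
      "row %d: non-positive or missing glucose (%s) for admission %s",
      bad[1], obs[[gl_col]][bad[1]], obs$admission_id[bad[1]]))

  observations <- data.frame(
    admission_id = obs$admission_id,
    t_minutes = t_minutes,
    glucose = glucose,
    source = if ("source" %in% names(obs)) as.character(obs$source)
             else rep("POC", nrow(obs)),
    stringsAsFactors = FALSE)

  unsorted <- stats::ave(t_minutes, obs$admission_id,
                         FUN = function(t) c(0, diff(t)))
  bad <- which(unsorted < 0)
  if (length(bad))
    validation_error(sprintf(
      "row %d: timestamps not sorted within admission %s",
      bad[1], obs$admission_id[bad[1]]))

  cov_file <- file.path(path, "covariates.csv")
  covariates <- if (file.exists(cov_file))
    data.table::setDF(data.table::fread(cov_file, colClasses = list(
      character = "admission_id"))) else NULL
  if (!is.null(admissions)) {
    for (fld in c("home_insulin", "home_antihyperglycemic"))
      if (fld %in% names(admissions))
        admissions[[fld]] <- as.logical(admissions[[fld]])
  }
  if (!is.null(covariates)) {
    if ("npo" %in% names(covariates))
      covariates$npo <- as.logical(covariates$npo)
    for (fld in setdiff(names(covariates), c("admission_id", "npo")))
      covariates[[fld]] <- as.numeric(covariates[[fld]])
  }

  structure(list(admissions = admissions, observations = observations,
                 covariates = covariates, config = NULL),
            class = "bg_cohort")
}
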