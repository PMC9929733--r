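#' Reading-level exclusion cascade for sparse inpatient glucose streams
#'
#' Point-of-care glucose streams contain bursts of near-simultaneous
#' readings (repeat checks of the same glycemic event) that would inflate
#' the apparent accuracy of any next-value predictor.  The cascade applied
#' here, in fixed order, is:
#'
#' 1. **5-minute block deduplication** ([assign_blocks()], [dedup_blocks()]):
#'    each reading is assigned to the wall-clock-aligned 5-minute window
#'    containing it (a 12:16 and a 12:18 reading both fall in the 12:15
#'    window); only the earliest reading per window is kept.
#' 2. **90-minute adjacency exclusion** ([exclude_adjacent()]): a reading
#'    whose immediate predecessor *and* successor (in the deduplicated
#'    sequence) are both within 90 minutes is dropped as a repeat
#'    measurement of the same episode.  The rule is a single simultaneous
#'    pass against the pre-removal neighbor structure, not iterated.
#' 3. **10-hour next-gap rule** ([mark_index_eligibility()]): a surviving
#'    reading whose next surviving reading arrives more than 10 hours later
#'    is not used as an index (prediction-origin) observation, but it
#'    remains available as lookback history for later readings.
#'
#' All boundaries are inclusive: "within 90 minutes" means a gap of at most
#' 90.0 minutes, and the index rule admits target gaps of at most 600.0
#' minutes.
#'
#' @param observations data.frame with columns `admission_id`, `t_minutes`,
#'   `glucose` (and optionally `clock_minutes`), sorted by time within
#'   admission.
#' @param admissions optional admission-level data.frame with
#'   `admit_clock_min`, used to anchor 5-minute blocks to the wall clock.
#'   Without it (and without a `clock_minutes` column) blocks are anchored
#'   at `t_minutes = 0`.
#' @return `assign_blocks()`: the observations with a `block_index` column
#'   (integer index of the 5-minute wall-clock window) and an `exclusion`
#'   column initialized to `"none"`.
#' @name preprocess-steps
NULL

#' @rdname preprocess-steps
#' @export
assign_blocks <- function(observations, admissions = NULL) {
  obs <- as.data.frame(observations)
  if (!all(c("admission_id", "t_minutes") %in% names(obs)))
    contract_error("observations need admission_id and t_minutes columns")
  dt <- stats::ave(obs$t_minutes, obs$admission_id,
                   FUN = function(t) c(0, diff(t)))
  if (any(dt < 0))
    validation_error("observations are not sorted by time within admission")

  clock <- if ("clock_minutes" %in% names(obs)) {
    obs$clock_minutes
  } else if (!is.null(admissions) && "admit_clock_min" %in% names(admissions)) {
    obs$t_minutes + admissions$admit_clock_min[
      match(obs$admission_id, admissions$admission_id)]
  } else {
    obs$t_minutes
  }
  obs$clock_minutes <- clock
  obs$block_index <- as.integer(floor(clock / 5))
  if (!"exclusion" %in% names(obs))
    obs$exclusion <- rep("none", nrow(obs))
  obs
}

#' @rdname preprocess-steps
#' @return `dedup_blocks()`: the observations with later readings in an
#'   already-occupied (admission, block) pair flagged `"duplicate_block"`;
#'   ties on identical timestamps are broken by input order.
#' @export
dedup_blocks <- function(observations) {
  obs <- as.data.frame(observations)
  if (!"block_index" %in% names(obs))
    contract_error("run assign_blocks() before dedup_blocks()")
  dup <- duplicated(data.frame(obs$admission_id, obs$block_index))
  obs$exclusion[dup & obs$exclusion == "none"] <- "duplicate_block"
  obs
}

#' @rdname preprocess-steps
#' @return `exclude_adjacent()`: the observations with readings whose
#'   deduplicated neighbors are both within 90 minutes flagged
#'   `"adjacency_90min"`; the first and last readings of an admission are
#'   never flagged.
#' @export
exclude_adjacent <- function(observations) {
  obs <- as.data.frame(observations)
  live <- which(obs$exclusion == "none")
  if (!length(live)) return(obs)
  d <- data.table::data.table(row = live,
                              admission_id = obs$admission_id[live],
                              t = obs$t_minutes[live])
  d[, `:=`(gap_prev = t - data.table::shift(t, 1L),
           gap_next = data.table::shift(t, -1L) - t),
    by = "admission_id"]
  flag <- d[!is.na(gap_prev) & !is.na(gap_next) &
              gap_prev <= 90 & gap_next <= 90, row]
  obs$exclusion[flag] <- "adjacency_90min"
  obs
}

#' @rdname preprocess-steps
#' @return `mark_index_eligibility()`: a list with the observations
#'   (surviving readings whose next surviving reading is more than 10 hours
#'   away flagged `"no_target_gt_10h"` — such readings stay in lookback
#'   history but are not prediction origins) and the `pairs` data.frame of
#'   index observations matched to their next-BG targets (`admission_id`,
#'   `obs_row`, `index_t_minutes`, `index_bg`, `target_bg`,
#'   `target_gap_hours`).
#' @export
mark_index_eligibility <- function(observations) {
  obs <- as.data.frame(observations)
  live <- which(obs$exclusion == "none")
  d <- data.table::data.table(row = live,
                              admission_id = obs$admission_id[live],
                              t = obs$t_minutes[live],
                              glucose = obs$glucose[live])
  d[, `:=`(gap_next = data.table::shift(t, -1L) - t,
           target = data.table::shift(glucose, -1L)),
    by = "admission_id"]
  no_target <- d[!is.na(gap_next) & gap_next > 600, row]
  obs$exclusion[no_target] <- "no_target_gt_10h"
  idx <- d[!is.na(gap_next) & gap_next <= 600]
  pairs <- data.frame(admission_id = idx$admission_id,
                      obs_row = idx$row,
                      index_t_minutes = idx$t,
                      index_bg = idx$glucose,
                      target_bg = idx$target,
                      target_gap_hours = idx$gap_next / 60,
                      stringsAsFactors = FALSE)
  list(observations = obs, pairs = pairs)
}

#' Preprocess a whole cohort (or one admission)
#'
#' Applies the full exclusion cascade — block assignment, block
#' deduplication, 90-minute adjacency exclusion, 10-hour index-eligibility —
#' and reconciles the counts into a report.
#'
#' @param cohort a `bg_cohort` (or anything with `$observations` and
#'   `$admissions`).
#' @return an object of class `bg_preprocessed`: list with `observations`
#'   (exclusion-flagged), `pairs` (index/target prediction pairs),
#'   `report` (a `bg_preprocess_report`), plus the cohort's `admissions`
#'   and `covariates` carried through.
#' @export
preprocess_cohort <- function(cohort) {
  obs <- cohort$observations
  counts <- table(obs$admission_id)
  if (any(counts < 4))
    bg_error(sprintf(
      "admission %s has %d readings; inclusion requires at least 4",
      names(counts)[counts < 4][1], min(counts)), "bg_inclusion_error")

  obs <- assign_blocks(obs, cohort$admissions)
  obs <- dedup_blocks(obs)
  obs <- exclude_adjacent(obs)
  marked <- mark_index_eligibility(obs)
  obs <- marked$observations

  excl <- obs$exclusion
  live <- excl %in% c("none", "no_target_gt_10h")
  is_last <- !duplicated(obs$admission_id[live], fromLast = TRUE)
  report <- structure(list(
    n_input = nrow(obs),
    n_duplicate_block = sum(excl == "duplicate_block"),
    n_adjacency = sum(excl == "adjacency_90min"),
    n_no_target = sum(excl == "no_target_gt_10h"),
    n_terminal = sum(excl[live] == "none" & is_last),
    n_retained_index = nrow(marked$pairs)), class = "bg_preprocess_report")
  stopifnot(report$n_input == report$n_retained_index +
              report$n_duplicate_block + report$n_adjacency +
              report$n_no_target + report$n_terminal)

  structure(list(observations = obs, pairs = marked$pairs, report = report,
                 admissions = cohort$admissions,
                 covariates = cohort$covariates),
            class = "bg_preprocessed")
}

#' @rdname preprocess_cohort
#' @param admission a `bg_admission` (from [generate_admission()]) or a
#'   data.frame of one admission's observations.
#' @export
preprocess_admission <- function(admission) {
  if (inherits(admission, "bg_admission")) {
    cohort <- list(observations = admission$observations,
                   admissions = admission$admission,
                   covariates = admission$covariates)
  } else {
    cohort <- list(observations = as.data.frame(admission),
                   admissions = NULL, covariates = NULL)
  }
  preprocess_cohort(cohort)
}

#' @export
print.bg_preprocess_report <- function(x, ...) {
  cat("<bg_preprocess_report>\n")
  cat(sprintf("  input readings:        %d\n", x$n_input))
  cat(sprintf("  duplicate 5-min block: %d\n", x$n_duplicate_block))
  cat(sprintf("  90-min adjacency:      %d\n", x$n_adjacency))
  cat(sprintf("  next gap > 10 h:       %d (kept as history)\n",
              x$n_no_target))
  cat(sprintf("  terminal readings:     %d (kept as history)\n",
              x$n_terminal))
  cat(sprintf("  eligible index rows:   %d\n", x$n_retained_index))
  invisible(x)
}

#' @export
print.bg_preprocessed <- function(x, ...) {
  print(x$report)
  invisible(x)
}
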