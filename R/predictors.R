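#' Predictor battery configuration
#'
#' The default battery is 24 predictors: 14 trailing moving averages (0.5 to
#' 72 hours), 7 rolling regressions (3 to 500 observations), recursive
#' regression (all readings since admission), the index reading itself
#' (sample-and-hold) and the previous reading.
#'
#' @param ma_windows_hours strictly increasing positive moving-average
#'   windows, in hours.
#' @param rr_orders strictly increasing integer rolling-regression orders
#'   (number of most recent observations), each at least 2.
#' @param include_recursive,include_sample_and_hold,include_previous_bg
#'   switches for the three non-windowed predictors.
#' @return an object of class `bg_predictor_config` whose `labels` field
#'   gives the column names emitted by [build_prediction_rows()]
#'   (`ma_0.5h`, ..., `rr_3`, ..., `recursive`, `index_bg`, `prev_bg`).
#' @export
predictor_config <- function(ma_windows_hours = c(0.5, 1, 1.5, 2, 4, 8, 12,
                                                  16, 20, 24, 36, 48, 60, 72),
                             rr_orders = c(3, 4, 5, 10, 25, 100, 500),
                             include_recursive = TRUE,
                             include_sample_and_hold = TRUE,
                             include_previous_bg = TRUE) {
  if (length(ma_windows_hours) &&
      (any(ma_windows_hours <= 0) || any(diff(ma_windows_hours) <= 0)))
    config_error("ma_windows_hours", "must be positive, strictly increasing")
  if (length(rr_orders)) {
    if (any(rr_orders != round(rr_orders)) || any(rr_orders < 2) ||
        any(diff(rr_orders) <= 0))
      config_error("rr_orders",
                   "must be strictly increasing integers, each >= 2")
    rr_orders <- as.integer(rr_orders)
  }
  labels <- c(if (length(ma_windows_hours))
                paste0("ma_", ma_windows_hours, "h"),
              if (length(rr_orders)) paste0("rr_", rr_orders),
              if (include_recursive) "recursive",
              if (include_sample_and_hold) "index_bg",
              if (include_previous_bg) "prev_bg")
  structure(list(ma_windows_hours = ma_windows_hours,
                 rr_orders = rr_orders,
                 include_recursive = include_recursive,
                 include_sample_and_hold = include_sample_and_hold,
                 include_previous_bg = include_previous_bg,
                 labels = labels),
            class = "bg_predictor_config")
}

check_history <- function(history, index_obs) {
  if (is.null(history) || nrow(history) == 0L)
    contract_error("history must contain at least the index reading")
  keep <- history$t_minutes <= index_obs$t_minutes + 1e-9
  h <- history[keep, , drop = FALSE]
  if (nrow(h) == 0L || abs(h$t_minutes[nrow(h)] - index_obs$t_minutes) > 1e-9)
    h <- rbind(h, data.frame(t_minutes = index_obs$t_minutes,
                             glucose = index_obs$glucose))
  h
}

#' Single-observation time-series predictors
#'
#' Reference implementations of the next-BG predictors for one index
#' observation.  `history` is a data.frame with `t_minutes` and `glucose`
#' containing all retained readings of the admission at or before the index
#' time (the index reading itself may be included; it is appended if
#' missing).  [build_prediction_rows()] computes the same quantities for a
#' whole cohort.
#'
#' * `moving_average_predict()`: unweighted mean of all readings with
#'   timestamps in the closed window `[index_t - window, index_t]`,
#'   including the index reading; with no other reading in the window the
#'   prediction is the index value itself.
#' * `rolling_regression_predict()`: ordinary least squares of glucose on
#'   observation position `1..m` over the `m = min(n, available)` most
#'   recent readings up to and including the index, evaluated at position
#'   `m + 1`.  With fewer than 2 readings the prediction falls back to the
#'   index value.
#' * `recursive_regression_predict()`: rolling regression with `n` equal to
#'   all available readings since admission.
#' * `sample_and_hold_predict()`: the index value unchanged (zero-order
#'   hold).
#' * `previous_bg_predict()`: the retained reading immediately before the
#'   index; falls back to the index value when the index is the first
#'   reading.
#'
#' Regression extrapolation can leave the physical range on steeply falling
#' series, so all predictions are floored at 1 mg/dL.
#'
#' @param history data.frame with `t_minutes`, `glucose`.
#' @param index_obs list or one-row data.frame with `t_minutes`, `glucose`.
#' @param window_hours moving-average window length, hours.
#' @param n rolling-regression order (number of observations), `>= 2`.
#' @return predicted next BG in mg/dL.
#' @export
#' @examples
#' h <- data.frame(t_minutes = c(0, 180), glucose = c(100, 120))
#' moving_average_predict(h, list(t_minutes = 180, glucose = 120), 4)  # 110
moving_average_predict <- function(history, index_obs, window_hours) {
  h <- check_history(history, index_obs)
  lo <- index_obs$t_minutes - window_hours * 60
  max(1, mean(h$glucose[h$t_minutes >= lo - 1e-9]))
}

#' @rdname moving_average_predict
#' @export
rolling_regression_predict <- function(history, index_obs, n) {
  if (n < 2) contract_error("rolling regression needs n >= 2")
  h <- check_history(history, index_obs)
  m <- min(n, nrow(h))
  if (m < 2) return(max(1, index_obs$glucose))
  y <- h$glucose[(nrow(h) - m + 1):nrow(h)]
  x <- seq_len(m)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  max(1, mean(y) + slope * (m + 1 - mean(x)))
}

#' @rdname moving_average_predict
#' @export
recursive_regression_predict <- function(history, index_obs) {
  h <- check_history(history, index_obs)
  rolling_regression_predict(h, index_obs, n = max(2L, nrow(h)))
}

#' @rdname moving_average_predict
#' @export
sample_and_hold_predict <- function(index_obs) {
  max(1, index_obs$glucose)
}

#' @rdname moving_average_predict
#' @export
previous_bg_predict <- function(history, index_obs) {
  h <- check_history(history, index_obs)
  before <- which(h$t_minutes < index_obs$t_minutes - 1e-9)
  if (!length(before)) return(max(1, index_obs$glucose))
  max(1, h$glucose[max(before)])
}

#' Build the prediction-row table for a preprocessed cohort
#'
#' Computes every configured predictor at every eligible index observation.
#' Lookback history is the post-exclusion sequence: readings removed by
#' block deduplication or the 90-minute adjacency rule never enter a
#' window, while readings that merely fail index eligibility (10-hour rule,
#' terminal readings) do remain available as history.
#'
#' @param pre a `bg_preprocessed` object from [preprocess_cohort()].
#' @param config a [predictor_config()].
#' @param variability add trailing 24-hour CV and stratum columns (see
#'   [cv_24h()])?
#' @return data.frame of class `bg_prediction_rows`: identification columns
#'   (`admission_id`, `index_t_minutes`, `index_bg`, `target_bg`,
#'   `target_gap_hours`), one column per predictor label, `cv_24h` and
#'   `stratum` when requested, and any admission-level / per-observation
#'   covariates present in the cohort.
#' @export
build_prediction_rows <- function(pre, config = predictor_config(),
                                  variability = TRUE) {
  stopifnot(inherits(pre, "bg_preprocessed"),
            inherits(config, "bg_predictor_config"))
  pairs <- pre$pairs
  if (nrow(pairs) == 0L) {
    out <- cbind(pairs[, c("admission_id", "index_t_minutes", "index_bg",
                           "target_bg", "target_gap_hours")],
                 matrix(numeric(0), 0, length(config$labels),
                        dimnames = list(NULL, config$labels)))
    class(out) <- c("bg_prediction_rows", "data.frame")
    return(out)
  }
  obs <- pre$observations
  live <- obs$exclusion %in% c("none", "no_target_gt_10h")

  d <- data.table::data.table(
    admission_id = obs$admission_id[live],
    t = obs$t_minutes[live],
    y = obs$glucose[live],
    obs_row = which(live))
  idx_dt <- data.table::data.table(obs_row = pairs$obs_row,
                                   pair_id = seq_len(nrow(pairs)))
  d <- merge(d, idx_dt, by = "obs_row", all.x = TRUE, sort = FALSE)
  data.table::setorder(d, admission_id, t)

  res <- d[, admission_predictors(t, y, pair_id, config),
           by = "admission_id"]
  data.table::setorder(res, pair_id)
  id_cols <- c("admission_id", "obs_row", "index_t_minutes", "index_bg",
               "target_bg", "target_gap_hours")
  # the sample-and-hold predictor IS the index_bg id column; avoid a
  # duplicated column name
  pred_mat <- as.data.frame(res[, setdiff(config$labels, id_cols),
                                with = FALSE])
  out <- cbind(pairs[res$pair_id, id_cols], pred_mat)
  rownames(out) <- NULL

  if (variability) out <- add_variability(out, pre)
  out <- merge_covariates(out, pre)
  class(out) <- c("bg_prediction_rows", "data.frame")
  out
}

# Vectorized per-admission predictor computation.  t, y: the post-exclusion
# history sequence; pair_id is non-NA at index observations.
admission_predictors <- function(t, y, pair_id, config) {
  K <- length(y)
  idx <- which(!is.na(pair_id))
  out <- list(pair_id = pair_id[idx])
  i <- idx  # survivor-sequence positions of the index rows

  S1 <- cumsum(y)
  S0 <- c(0, S1)   # S0[k + 1] = sum of first k values
  # moving averages: closed window [t_i - w, t_i]
  for (w in config$ma_windows_hours) {
    j0 <- findInterval(t[i] - w * 60 - 1e-9, t) + 1L
    out[[paste0("ma_", w, "h")]] <-
      pmax(1, (S0[i + 1L] - S0[j0]) / (i - j0 + 1L))
  }

  # recursive regression: OLS over positions 1..i, evaluated at i + 1
  SJ <- cumsum(seq_len(K) * y)
  rec <- rep(NA_real_, length(i))
  m <- i
  sx <- m * (m + 1) / 2
  sxx <- m * (m + 1) * (2 * m + 1) / 6
  den <- m * sxx - sx^2
  slope <- ifelse(m >= 2, (m * SJ[i] - sx * S1[i]) / den, 0)
  inter <- (S1[i] - slope * sx) / pmax(m, 1)
  rec <- ifelse(m >= 2, inter + slope * (m + 1), y[i])

  # rolling regressions: exact sliding dot products for full windows,
  # recursive value where fewer than n readings are available
  for (n in config$rr_orders) {
    vals <- rec
    full <- which(i >= n)
    if (length(full)) {
      E <- stats::embed(y, n)            # row k = y[k+n-1], ..., y[k]
      rowidx <- i[full] - n + 1L
      sy <- E[rowidx, , drop = FALSE] %*% rep(1, n)
      sxy <- E[rowidx, , drop = FALSE] %*% (n:1)
      sx <- n * (n + 1) / 2
      sxx <- n * (n + 1) * (2 * n + 1) / 6
      slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
      vals[full] <- (sy - slope * sx) / n + slope * (n + 1)
    }
    out[[paste0("rr_", n)]] <- pmax(1, as.numeric(vals))
  }
  if (config$include_recursive) out[["recursive"]] <- pmax(1, rec)
  if (config$include_sample_and_hold) out[["index_bg"]] <- pmax(1, y[i])
  if (config$include_previous_bg)
    out[["prev_bg"]] <- pmax(1, ifelse(i > 1L, y[pmax(i - 1L, 1L)], y[i]))
  out
}

merge_covariates <- function(rows, pre) {
  adm <- pre$admissions
  if (!is.null(adm)) {
    keep <- intersect(c("age", "sex", "race", "diabetes_dx", "home_insulin",
                        "home_antihyperglycemic"), names(adm))
    if (length(keep))
      rows <- cbind(rows, adm[match(rows$admission_id, adm$admission_id),
                              keep, drop = FALSE])
  }
  cov <- pre$covariates
  if (!is.null(cov)) {
    key_rows <- paste(rows$admission_id, rows$index_t_minutes)
    key_cov <- paste(cov$admission_id, cov$t_minutes)
    keep <- setdiff(names(cov), c("admission_id", "t_minutes"))
    rows <- cbind(rows, cov[match(key_rows, key_cov), keep, drop = FALSE])
  }
  rownames(rows) <- NULL
  rows
}
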