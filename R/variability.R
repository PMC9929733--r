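#' Trailing 24-hour coefficient of variation
#'
#' The coefficient of variation (CV = sample standard deviation / mean) of
#' all retained readings in the closed window ending at the index
#' observation and extending 24 hours back, including the index reading.
#' With fewer than two readings in the window the CV is undefined (`NA`).
#'
#' @param history data.frame with `t_minutes`, `glucose` (retained readings
#'   of the admission).
#' @param index_obs list or one-row data.frame with `t_minutes`, `glucose`.
#' @return the CV (dimensionless, `>= 0`) or `NA_real_`.
#' @export
#' @examples
#' h <- data.frame(t_minutes = c(0, 60), glucose = c(80, 120))
#' cv_24h(h, list(t_minutes = 60, glucose = 120))  # about 0.283
cv_24h <- function(history, index_obs) {
  h <- check_history(history, index_obs)
  win <- h$glucose[h$t_minutes >= index_obs$t_minutes - 24 * 60 - 1e-9]
  if (length(win) < 2L) return(NA_real_)
  sd(win) / mean(win)
}

#' Glycemic-variability stratum from a 24-hour CV
#'
#' Boundaries belong to the lower stratum: low is CV of at most 0.15,
#' medium is CV in (0.15, 0.30], high is CV in (0.30, 0.45], very high is
#' CV above 0.45.  An undefined CV maps to `"unclassified"`.
#'
#' @param cv numeric vector of CVs (may contain `NA`).
#' @return character vector with values in `low`, `medium`, `high`,
#'   `very_high`, `unclassified`.
#' @export
#' @examples
#' assign_stratum(c(0.15, 0.300001, NA))
assign_stratum <- function(cv) {
  if (any(!is.na(cv) & cv < 0))
    contract_error("CV cannot be negative")
  out <- rep("unclassified", length(cv))
  ok <- !is.na(cv)
  out[ok & cv <= 0.15] <- "low"
  out[ok & cv > 0.15 & cv <= 0.30] <- "medium"
  out[ok & cv > 0.30 & cv <= 0.45] <- "high"
  out[ok & cv > 0.45] <- "very_high"
  out
}

#' Add CV and stratum columns to a prediction-row table
#'
#' Vectorized equivalent of calling [cv_24h()] and [assign_stratum()] at
#' every index observation, using the same post-exclusion history sequence
#' as the predictors.
#'
#' @param rows prediction rows (from [build_prediction_rows()]).
#' @param pre the `bg_preprocessed` object the rows were built from.
#' @return `rows` with `cv_24h` and `stratum` columns.
#' @export
add_variability <- function(rows, pre) {
  obs <- pre$observations
  live <- obs$exclusion %in% c("none", "no_target_gt_10h")
  d <- data.table::data.table(admission_id = obs$admission_id[live],
                              t = obs$t_minutes[live],
                              y = obs$glucose[live],
                              obs_row = which(live))
  data.table::setorder(d, admission_id, t)
  res <- d[, {
    S1 <- c(0, cumsum(y)); S2 <- c(0, cumsum(y^2))
    i <- seq_along(y)
    j0 <- findInterval(t - 24 * 60 - 1e-9, t) + 1L
    n <- i - j0 + 1L
    sy <- S1[i + 1L] - S1[j0]
    syy <- S2[i + 1L] - S2[j0]
    v <- pmax(0, (syy - sy^2 / n) / pmax(n - 1L, 1L))
    list(obs_row = obs_row,
         cv = ifelse(n >= 2L, sqrt(v) / (sy / n), NA_real_))
  }, by = "admission_id"]
  cv <- res$cv[match(rows$obs_row, res$obs_row)]
  rows$cv_24h <- cv
  rows$stratum <- assign_stratum(cv)
  rows
}
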