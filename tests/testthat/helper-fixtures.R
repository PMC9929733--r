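# Shared fixtures and independent oracles, built in code.

# Small default-structure cohort for structural tests.
small_cohort <- function(n = 50, seed = 101, ...) {
  generate_cohort(cohort_config(n_admissions = n, seed = seed, ...))
}

# The worked preprocessing example: readings at 2:46, 2:48, 6:33, 6:45 and
# 6:52 PM (glucose 50, 51, 90, 68, 75 mg/dL).  Encoded as minutes since an
# admission that starts at midnight, so wall-clock and relative time agree.
figure_example_observations <- function() {
  data.frame(
    admission_id = "EX1",
    t_minutes = c(14 * 60 + 46, 14 * 60 + 48, 18 * 60 + 33,
                  18 * 60 + 45, 18 * 60 + 52),
    glucose = c(50, 51, 90, 68, 75),
    source = "POC",
    stringsAsFactors = FALSE)
}

# Hand-built admission: readings every 4 h exactly, constant-free values.
regular_admission <- function(glucose, gap_minutes = 240) {
  data.frame(admission_id = "REG1",
             t_minutes = gap_minutes * (seq_along(glucose) - 1),
             glucose = glucose, source = "POC",
             stringsAsFactors = FALSE)
}

# --- independent oracles ----------------------------------------------------

# Brute-force moving average: explicit mean over the closed window.
oracle_ma <- function(t, y, i, window_hours) {
  sel <- t >= t[i] - window_hours * 60 & t <= t[i]
  max(1, mean(y[sel & seq_along(t) <= i]))
}

# Brute-force rolling regression via explicit normal equations.
oracle_rr <- function(y, i, n) {
  m <- min(n, i)
  if (m < 2) return(max(1, y[i]))
  yy <- y[(i - m + 1):i]
  X <- cbind(1, seq_len(m))
  beta <- solve(t(X) %*% X, t(X) %*% yy)
  max(1, beta[1] + beta[2] * (m + 1))
}

# Reference CV over the trailing 24-hour window.
oracle_cv <- function(t, y, i) {
  sel <- t >= t[i] - 24 * 60 & t <= t[i] & seq_along(t) <= i
  if (sum(sel) < 2) return(NA_real_)
  sd(y[sel]) / mean(y[sel])
}

# Maximum relative disagreement between the vectorized predictor battery
# and the brute-force oracles, per predictor label, over a whole cohort.
battery_oracle_errors <- function(pre, cfg = predictor_config()) {
  rows <- build_prediction_rows(pre, cfg, variability = FALSE)
  labs <- c(paste0("ma_", cfg$ma_windows_hours, "h"),
            paste0("rr_", cfg$rr_orders), "recursive", "prev_bg")
  worst <- setNames(numeric(length(labs)), labs)
  for (id in unique(rows$admission_id)) {
    s <- survivors(pre, id)
    t <- s$t_minutes; y <- s$glucose
    sub <- rows[rows$admission_id == id, ]
    pos <- match(sub$index_t_minutes, t)
    for (k in seq_len(nrow(sub))) {
      i <- pos[k]
      ref <- c(vapply(cfg$ma_windows_hours,
                      function(w) oracle_ma(t, y, i, w), 0),
               vapply(cfg$rr_orders, function(n) oracle_rr(y, i, n), 0),
               oracle_rr(y, i, i),
               if (i > 1) y[i - 1] else y[i])
      got <- vapply(labs, function(l) sub[[l]][k], 0)
      worst <- pmax(worst, abs(got - ref) / pmax(abs(ref), 1e-12))
    }
  }
  worst
}

# Survivor (post-exclusion history) sequence for one admission.
survivors <- function(pre, id) {
  obs <- pre$observations
  obs[obs$admission_id == id &
        obs$exclusion %in% c("none", "no_target_gt_10h"), ]
}
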