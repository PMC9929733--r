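test_that("moving average matches hand-computed examples", {
  h <- data.frame(t_minutes = c(0, 180), glucose = c(100, 120))
  idx <- list(t_minutes = 180, glucose = 120)
  expect_equal(moving_average_predict(h, idx, 4), 110)
  # no other reading in the window: prediction is the index BG
  expect_equal(moving_average_predict(h, idx, 2), 120)
  # reading exactly on the window edge is included (closed window)
  expect_equal(moving_average_predict(h, idx, 3), 110)
  # constant series: every window returns the constant
  hc <- data.frame(t_minutes = c(0, 60, 120), glucose = rep(141, 3))
  for (w in c(0.5, 1, 2, 24))
    expect_equal(moving_average_predict(hc, list(t_minutes = 120,
                                                 glucose = 141), w), 141)
})

test_that("rolling regression matches hand-computed examples", {
  h <- data.frame(t_minutes = c(0, 240, 480), glucose = c(100, 110, 120))
  idx <- list(t_minutes = 480, glucose = 120)
  expect_equal(rolling_regression_predict(h, idx, 3), 130)
  # two points extrapolate linearly
  h2 <- data.frame(t_minutes = c(0, 240), glucose = c(100, 90))
  expect_equal(rolling_regression_predict(h2, list(t_minutes = 240,
                                                   glucose = 90), 2), 80)
  # constant series: zero slope at any order
  hc <- data.frame(t_minutes = c(0, 240, 480, 720), glucose = rep(125, 4))
  for (n in c(2, 3, 4, 100))
    expect_equal(rolling_regression_predict(hc, list(t_minutes = 720,
                                                     glucose = 125), n), 125)
  expect_error(rolling_regression_predict(h, idx, 1), "n >= 2",
               class = "bg_contract_error")
})

test_that("recursive regression equals rolling regression on all readings", {
  h <- data.frame(t_minutes = c(0, 240, 480), glucose = c(100, 110, 120))
  idx <- list(t_minutes = 480, glucose = 120)
  expect_identical(recursive_regression_predict(h, idx),
                   rolling_regression_predict(h, idx, 3))
  set.seed(1)
  h40 <- data.frame(t_minutes = 240 * (0:39),
                    glucose = round(rnorm(40, 150, 30)))
  idx40 <- list(t_minutes = h40$t_minutes[40], glucose = h40$glucose[40])
  expect_equal(recursive_regression_predict(h40, idx40),
               rolling_regression_predict(h40, idx40, 40), tolerance = 1e-12)
})

test_that("sample-and-hold and previous-BG behave as documented", {
  expect_identical(sample_and_hold_predict(list(glucose = 141)), 141)
  expect_identical(sample_and_hold_predict(list(glucose = 54)), 54)
  h <- data.frame(t_minutes = c(0, 240), glucose = c(100, 90))
  expect_equal(previous_bg_predict(h, list(t_minutes = 240, glucose = 90)),
               100)
  # first reading: falls back to the index itself
  expect_equal(previous_bg_predict(h[2, ], list(t_minutes = 240,
                                                glucose = 90)), 90)
})

test_that("empty pair list yields an empty but fully-labelled row table", {
  cohort <- small_cohort(n = 3, seed = 21)
  pre <- preprocess_cohort(cohort)
  pre$pairs <- pre$pairs[0, ]
  rows <- build_prediction_rows(pre)
  expect_identical(nrow(rows), 0L)
  expect_true(all(predictor_config()$labels %in% names(rows)))
})

test_that("prediction rows carry every predictor with valid values", {
  pre <- preprocess_cohort(small_cohort(n = 30, seed = 22))
  rows <- build_prediction_rows(pre)
  labels <- predictor_config()$labels
  expect_length(labels, 24L)
  expect_true(all(labels %in% names(rows)))
  for (lab in labels)
    expect_true(all(is.finite(rows[[lab]]) & rows[[lab]] > 0), info = lab)
  expect_true(all(rows$target_gap_hours > 0 & rows$target_gap_hours <= 10))

  # 5 readings 4 h apart: 4 rows, 24 predictor entries each
  pre5 <- preprocess_admission(regular_admission(c(100, 120, 110, 130, 140)))
  rows5 <- build_prediction_rows(pre5)
  expect_identical(nrow(rows5), 4L)
  expect_identical(sum(names(rows5) %in% labels), 24L)
  # first index row: previous-BG falls back to the index BG
  expect_equal(rows5$prev_bg[1], rows5$index_bg[1])
  expect_equal(rows5$prev_bg[2], 100)
})

test_that("vectorized battery matches brute-force oracles on random cohorts", {
  pre <- preprocess_cohort(small_cohort(n = 25, seed = 23))
  err <- battery_oracle_errors(pre, predictor_config())
  expect_lt(max(err), 1e-9)
})

test_that("recursive regression equals RR(500) up to 500 readings", {
  pre <- preprocess_cohort(small_cohort(n = 40, seed = 24))
  rows <- build_prediction_rows(pre, variability = FALSE)
  live <- pre$observations[pre$observations$exclusion %in%
                             c("none", "no_target_gt_10h"), ]
  n_surv <- table(live$admission_id)
  small_adm <- names(n_surv)[n_surv <= 500]
  expect_gt(length(small_adm), 30)
  sel <- rows$admission_id %in% small_adm
  expect_identical(rows$rr_500[sel], rows$recursive[sel])
  # beyond 500 readings the two genuinely diverge for late index rows
  big <- setdiff(rows$admission_id, small_adm)
  if (length(big))
    expect_false(all(rows$rr_500[rows$admission_id %in% big] ==
                       rows$recursive[rows$admission_id %in% big]))
})

test_that("enlarging an MA window never removes readings from the set", {
  pre <- preprocess_cohort(small_cohort(n = 15, seed = 25))
  rows <- build_prediction_rows(pre, variability = FALSE)
  for (id in unique(rows$admission_id)) {
    s <- survivors(pre, id)
    sub <- rows[rows$admission_id == id, ]
    pos <- match(sub$index_t_minutes, s$t_minutes)
    for (k in seq_len(nrow(sub))) {
      counts <- vapply(predictor_config()$ma_windows_hours, function(w)
        sum(s$t_minutes >= sub$index_t_minutes[k] - w * 60 &
              seq_len(nrow(s)) <= pos[k]), 0)
      expect_true(all(diff(counts) >= 0))
    }
  }
})

test_that("predictor config validates its grids", {
  expect_error(predictor_config(ma_windows_hours = c(2, 1)),
               "ma_windows_hours", class = "bg_config_error")
  expect_error(predictor_config(rr_orders = c(1, 3)), "rr_orders",
               class = "bg_config_error")
  labs <- predictor_config(ma_windows_hours = c(1, 2),
                           rr_orders = c(3, 5),
                           include_previous_bg = FALSE)$labels
  expect_identical(labs, c("ma_1h", "ma_2h", "rr_3", "rr_5", "recursive",
                           "index_bg"))
})
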