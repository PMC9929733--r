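test_that("identical config and seed give identical cohorts", {
  a <- small_cohort(n = 20, seed = 5)
  b <- small_cohort(n = 20, seed = 5)
  expect_identical(a$observations, b$observations)
  expect_identical(a$admissions, b$admissions)
  expect_identical(a$covariates, b$covariates)
  c2 <- small_cohort(n = 20, seed = 6)
  expect_false(identical(a$observations, c2$observations))
})

test_that("generated admissions satisfy their invariants", {
  cohort <- small_cohort(n = 200, seed = 8)
  counts <- table(cohort$observations$admission_id)
  expect_true(all(counts >= 4))
  gaps <- unlist(tapply(cohort$observations$t_minutes,
                        cohort$observations$admission_id, diff))
  expect_true(all(gaps > 0))
  expect_true(all(cohort$observations$glucose >= 10 &
                    cohort$observations$glucose <= 1000))
  # one covariate record per observation
  expect_identical(nrow(cohort$covariates), nrow(cohort$observations))
})

test_that("config validation names the offending field", {
  expect_error(cohort_config(n_admissions = 0), "n_admissions",
               class = "bg_config_error")
  expect_error(cohort_config(stratum_weights = c(0.5, 0.5, 0.2, -0.2)),
               "stratum_weights", class = "bg_config_error")
  expect_error(cohort_config(ar_coefficient = 1), "ar_coefficient",
               class = "bg_config_error")
  expect_error(cohort_config(gap_mixture_params = list(
    weights = c(0.5, 0.6), meanlog = c(0, 1), sdlog = c(1, 1))),
    "weights", class = "bg_config_error")
  expect_error(
    cohort_config(reading_count_params = list(meanlog = 2, sdlog = -1)),
    "sdlog", class = "bg_config_error")
})

test_that("reading counts target the published median and IQR shape", {
  cohort <- small_cohort(n = 1000, seed = 31)
  counts <- as.integer(table(cohort$observations$admission_id))
  expect_gte(median(counts), 10)
  expect_lte(median(counts), 14)
  expect_gte(min(counts), 4)
})

test_that("gap percentiles match the target distribution within 20%", {
  cohort <- small_cohort(n = 1000, seed = 32, covariate_flags = FALSE)
  gaps <- unlist(tapply(cohort$observations$t_minutes,
                        cohort$observations$admission_id, diff)) / 60
  q <- quantile(gaps, c(0.05, 0.25, 0.50, 0.75, 0.95))
  target <- c(0.58, 2.48, 3.88, 4.88, 8.23)
  expect_true(all(abs(q / target - 1) < 0.20),
              info = paste(round(q, 3), collapse = ", "))
})

test_that("per-admission mean BG targets median 141 (IQR 117-179)", {
  cohort <- small_cohort(n = 1000, seed = 33, covariate_flags = FALSE)
  means <- tapply(cohort$observations$glucose,
                  cohort$observations$admission_id, mean)
  expect_gt(median(means), 120)
  expect_lt(median(means), 165)
})

test_that("AR coefficient is recovered from a long admission", {
  cfg <- cohort_config(n_admissions = 1, seed = 9, ar_coefficient = 0.9,
                       reading_count_params = list(meanlog = log(5000),
                                                   sdlog = 1e-9, min = 4),
                       covariate_flags = FALSE)
  set.seed(99)
  adm <- generate_admission(cfg, "LONG1")
  y <- adm$observations$glucose
  rho_hat <- cor(y[-1], y[-length(y)])
  expect_lt(abs(rho_hat - 0.9), 0.05)

  # rho = 0: successive deviations uncorrelated
  cfg0 <- cohort_config(n_admissions = 1, seed = 9, ar_coefficient = 0,
                        reading_count_params = list(meanlog = log(5000),
                                                    sdlog = 1e-9, min = 4),
                        covariate_flags = FALSE)
  set.seed(100)
  adm0 <- generate_admission(cfg0, "LONG0")
  y0 <- adm0$observations$glucose
  expect_lt(abs(cor(y0[-1], y0[-length(y0)])), 0.05)
})

test_that("generator hits each requested variability stratum", {
  # "Can produce": a configuration built for stratum targeting — dense
  # reading schedule and mild autocorrelation, so the trailing-24h sample
  # CV is a precise estimate of the target, with targets at band centers.
  # very-high targets sit above the band floor because truncation at
  # 40 mg/dL clips the left tail and biases the realized CV downward
  dense_gaps <- list(weights = 1, meanlog = log(0.5), sdlog = 0.1)
  bands <- list(low = c(0, 0.15), medium = c(0.15, 0.30),
                high = c(0.30, 0.45), very_high = c(0.45, Inf))
  centers <- rbind(low = c(0.09, 0.12), medium = c(0.21, 0.24),
                   high = c(0.36, 0.39), very_high = c(0.60, 0.70))
  for (s in seq_along(bands)) {
    w <- numeric(4); w[s] <- 1
    cfg <- cohort_config(n_admissions = 150, seed = 40 + s,
                         stratum_weights = w,
                         gap_mixture_params = dense_gaps,
                         cv_target_ranges = centers,
                         ar_coefficient = 0,
                         reading_count_params = list(meanlog = log(60),
                                                     sdlog = 0.2, min = 4),
                         covariate_flags = FALSE)
    cohort <- generate_cohort(cfg)
    obs <- cohort$observations
    hits <- vapply(unique(obs$admission_id), function(id) {
      sub <- obs[obs$admission_id == id, ]
      i <- max(2L, ceiling(nrow(sub) / 2))
      cv <- oracle_cv(sub$t_minutes, sub$glucose, i)
      !is.na(cv) && cv > bands[[s]][1] && cv <= bands[[s]][2]
    }, TRUE)
    expect_gte(mean(hits), 0.80)
  }
})

test_that("low-variability config keeps realized CV below 0.15", {
  cfg <- cohort_config(n_admissions = 200, seed = 51,
                       stratum_weights = c(1, 0, 0, 0),
                       cv_target_ranges = rbind(low = c(0.06, 0.10),
                                                medium = c(0.19, 0.26),
                                                high = c(0.34, 0.41),
                                                very_high = c(0.48, 0.60)),
                       covariate_flags = FALSE)
  cohort <- generate_cohort(cfg)
  obs <- cohort$observations
  hits <- vapply(unique(obs$admission_id), function(id) {
    sub <- obs[obs$admission_id == id, ]
    cv <- oracle_cv(sub$t_minutes, sub$glucose,
                    max(2L, ceiling(nrow(sub) / 2)))
    !is.na(cv) && cv <= 0.15
  }, TRUE)
  expect_gte(mean(hits), 0.90)
})

test_that("cohort CSV round trip is field-identical", {
  dir <- withr::local_tempdir()
  cohort <- small_cohort(n = 3, seed = 77)
  write_cohort(cohort, dir)
  back <- read_cohort(dir)
  expect_identical(back$observations, cohort$observations)
  expect_identical(back$covariates$insulin_basal,
                   cohort$covariates$insulin_basal)
  expect_identical(back$admissions$diabetes_dx,
                   cohort$admissions$diabetes_dx)

  # empty cohort: header-only files round trip to zero rows
  dir2 <- withr::local_tempdir()
  empty <- cohort
  empty$observations <- cohort$observations[0, ]
  empty$admissions <- cohort$admissions[0, ]
  empty$covariates <- cohort$covariates[0, ]
  write_cohort(empty, dir2)
  expect_identical(nrow(read_cohort(dir2)$observations), 0L)
})

test_that("malformed observation files are rejected with the row named", {
  dir <- withr::local_tempdir()
  cohort <- small_cohort(n = 2, seed = 78)
  write_cohort(cohort, dir)
  obs <- read.csv(file.path(dir, "observations.csv"))
  obs$glucose_mgdl[3] <- -5
  write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "row 3", class = "bg_validation_error")

  # unsorted timestamps
  write_cohort(cohort, dir)
  obs <- read.csv(file.path(dir, "observations.csv"))
  obs$datetime[2] <- "2014-01-01T00:00:00"
  write.csv(obs, file.path(dir, "observations.csv"), row.names = FALSE)
  expect_error(read_cohort(dir), "not sorted", class = "bg_validation_error")
})

test_that("insulin hook lowers glucose when enabled", {
  base <- generate_cohort(cohort_config(n_admissions = 60, seed = 90,
                                        insulin_effect = 0))
  hooked <- generate_cohort(cohort_config(n_admissions = 60, seed = 90,
                                          insulin_effect = 5))
  on_insulin <- hooked$covariates$insulin_rapid > 0
  expect_gt(sum(on_insulin), 20)
  expect_lt(mean(hooked$observations$glucose[on_insulin] -
                   base$observations$glucose[on_insulin]), 0)
})
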