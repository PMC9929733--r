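test_that("blocks are wall-clock-aligned 5-minute windows", {
  obs <- data.frame(admission_id = "A", t_minutes = c(735, 736, 738, 740),
                    glucose = c(100, 110, 120, 130), source = "POC")
  # 12:15 PM = 735 min after midnight; 12:16 and 12:18 share its block
  b <- assign_blocks(obs)
  expect_identical(b$block_index, c(147L, 147L, 147L, 148L))

  # anchoring to an admission-level clock offset shifts blocks
  adm <- data.frame(admission_id = "A", admit_clock_min = 2L)
  b2 <- assign_blocks(data.frame(admission_id = "A", t_minutes = 734,
                                 glucose = 1, source = "POC"), adm)
  expect_identical(b2$block_index, 147L)

  expect_error(assign_blocks(data.frame(admission_id = "A",
                                        t_minutes = c(10, 5),
                                        glucose = c(1, 1))),
               "sorted", class = "bg_validation_error")
})

test_that("block deduplication keeps the earliest reading per block", {
  obs <- assign_blocks(data.frame(
    admission_id = "A", t_minutes = c(166, 168, 200, 201, 203),
    glucose = c(50, 51, 90, 91, 92), source = "POC"))
  d <- dedup_blocks(obs)
  expect_identical(d$exclusion,
                   c("none", "duplicate_block", "none", "duplicate_block",
                     "duplicate_block"))
})

test_that("90-minute adjacency rule flags interior sandwiched readings", {
  mk <- function(t) dedup_blocks(assign_blocks(
    data.frame(admission_id = "A", t_minutes = t,
               glucose = seq_along(t) + 100, source = "POC")))
  # gaps 12 and 7 minutes: middle reading flagged
  e <- exclude_adjacent(mk(c(1113, 1125, 1132)))
  expect_identical(e$exclusion, c("none", "adjacency_90min", "none"))
  # two readings: no reading has two neighbors
  expect_identical(exclude_adjacent(mk(c(0, 10)))$exclusion,
                   c("none", "none"))
  # successor gap 120 min > 90: nothing flagged
  expect_identical(exclude_adjacent(mk(c(0, 60, 180)))$exclusion,
                   rep("none", 3))
  # boundary: exactly 90 minutes on both sides counts as within
  expect_identical(exclude_adjacent(mk(c(0, 90, 180)))$exclusion[2],
                   "adjacency_90min")
})

test_that("10-hour rule removes index eligibility but keeps history", {
  obs <- exclude_adjacent(dedup_blocks(assign_blocks(data.frame(
    admission_id = "A",
    t_minutes = c(0, 240, 240 + 630, 240 + 630 + 240),
    glucose = c(100, 110, 120, 130), source = "POC"))))
  m <- mark_index_eligibility(obs)
  expect_identical(m$observations$exclusion,
                   c("none", "no_target_gt_10h", "none", "none"))
  expect_identical(m$pairs$index_bg, c(100, 120))
  expect_identical(m$pairs$target_bg, c(110, 130))
  # boundary: exactly 10 h is eligible; 10.5 h is not
  m2 <- mark_index_eligibility(exclude_adjacent(dedup_blocks(assign_blocks(
    data.frame(admission_id = "B", t_minutes = c(0, 600, 1230),
               glucose = c(1, 2, 3) * 100, source = "POC")))))
  expect_identical(m2$observations$exclusion,
                   c("none", "no_target_gt_10h", "none"))
})

test_that("the worked five-reading example excludes exactly 2:48 and 6:45", {
  pre <- preprocess_admission(figure_example_observations())
  expect_identical(pre$observations$exclusion,
                   c("none", "duplicate_block", "none", "adjacency_90min",
                     "none"))
  expect_identical(pre$report$n_duplicate_block, 1L)
  expect_identical(pre$report$n_adjacency, 1L)
  # surviving sequence 2:46, 6:33, 6:52 gives two index rows
  expect_identical(pre$pairs$index_bg, c(50, 90))
  expect_identical(pre$pairs$target_bg, c(90, 75))
})

test_that("regular 4-hour admissions survive untouched", {
  pre <- preprocess_admission(regular_admission(c(100, 120, 110, 130, 140)))
  expect_true(all(pre$observations$exclusion == "none"))
  expect_identical(nrow(pre$pairs), 4L)
  expect_identical(pre$report$n_terminal, 1L)
})

test_that("four identical-time readings dedup to one without an inclusion error", {
  obs <- data.frame(admission_id = "A", t_minutes = rep(100, 4),
                    glucose = c(100, 101, 102, 103), source = "POC")
  pre <- preprocess_admission(obs)
  expect_identical(pre$report$n_duplicate_block, 3L)
  expect_identical(pre$report$n_retained_index, 0L)
  expect_error(preprocess_admission(obs[1:3, ]), "at least 4",
               class = "bg_inclusion_error")
})

test_that("preprocessing is idempotent and order-preserving", {
  cohort <- small_cohort(n = 40, seed = 13)
  pre <- preprocess_cohort(cohort)
  clean <- pre$observations[pre$observations$exclusion %in%
                              c("none", "no_target_gt_10h"),
                            c("admission_id", "t_minutes", "glucose",
                              "source")]
  # the raw-inclusion screen (>= 4 readings) applies to raw admissions
  keep <- names(which(table(clean$admission_id) >= 4))
  clean <- clean[clean$admission_id %in% keep, ]
  rownames(clean) <- NULL
  again <- preprocess_cohort(list(observations = clean,
                                  admissions = cohort$admissions))
  expect_identical(again$report$n_duplicate_block, 0L)
  expect_identical(again$report$n_adjacency, 0L)
  expect_identical(again$observations$t_minutes, clean$t_minutes)
  # order preserved
  expect_identical(order(again$observations$admission_id,
                         again$observations$t_minutes),
                   seq_len(nrow(clean)))
})

test_that("report counts every input reading exactly once", {
  for (seed in c(1, 2, 3)) {
    cohort <- small_cohort(n = 30, seed = seed)
    r <- preprocess_cohort(cohort)$report
    expect_identical(r$n_input, nrow(cohort$observations))
    expect_identical(r$n_input,
                     r$n_retained_index + r$n_duplicate_block +
                       r$n_adjacency + r$n_no_target + r$n_terminal)
  }
})

test_that("no retained pair exceeds 10 h and no two survivors share a block", {
  cohort <- small_cohort(n = 60, seed = 14)
  pre <- preprocess_cohort(cohort)
  expect_true(all(pre$pairs$target_gap_hours > 0 &
                    pre$pairs$target_gap_hours <= 10))
  live <- pre$observations[pre$observations$exclusion %in%
                             c("none", "no_target_gt_10h"), ]
  expect_false(any(duplicated(live[, c("admission_id", "block_index")])))
})
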