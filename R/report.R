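#' Render a human-readable pipeline summary
#'
#' Assembles the stage outputs in `out_dir` into `report.md`: the
#' predictor-correlation table (overall and by variability stratum), the
#' Clarke Error Grid zone table, the learner cross-validation table when
#' present (with a notice when absent), plus two figures — an error-grid
#' scatter with the zone boundaries drawn, and a predictor-overlay trace
#' for one example admission.
#'
#' @param out_dir a directory populated by [run_pipeline()].
#' @return the path of `report.md`, invisibly.
#' @export
render_report <- function(out_dir) {
  t2_f <- file.path(out_dir, "table2_correlation.csv")
  t3_f <- file.path(out_dir, "table3_clarke.csv")
  if (!file.exists(t2_f) || !file.exists(t3_f))
    bg_error("evaluation tables not found; run the evaluate stage first",
             "bg_stage_error")
  rows <- load_prediction_rows(out_dir)
  if (nrow(rows) == 0L)
    bg_error("no prediction rows available; cannot render a report",
             "bg_stage_error")
  t2 <- data.table::setDF(data.table::fread(t2_f))
  t3 <- data.table::setDF(data.table::fread(t3_f))

  lines <- c("# Next-BG prediction report", "",
             sprintf("Prediction rows: %d; admissions: %d.", nrow(rows),
                     length(unique(rows$admission_id))), "")

  lines <- c(lines, "## Predictor correlation (squared Pearson) by stratum",
             "", md_corr_table(t2), "")
  lines <- c(lines, "## Clarke Error Grid zone proportions", "",
             md_clarke_table(t3), "")

  t4_f <- file.path(out_dir, "table4_cv.csv")
  if (file.exists(t4_f)) {
    t4 <- data.table::setDF(data.table::fread(t4_f))
    lines <- c(lines, "## Cross-validated learners", "", md_cv_table(t4), "")
  } else {
    lines <- c(lines, "## Cross-validated learners", "",
               "_ml-compare stage not run; table omitted._", "")
  }

  fig1 <- file.path(out_dir, "fig_error_grid.png")
  plot_error_grid_file(rows, fig1)
  fig2 <- file.path(out_dir, "fig_admission_overlay.png")
  plot_admission_overlay_file(rows, fig2)
  lines <- c(lines, "## Figures", "",
             "![Clarke error grid](fig_error_grid.png)", "",
             "![Example admission](fig_admission_overlay.png)", "")

  path <- file.path(out_dir, "report.md")
  writeLines(lines, path)
  invisible(path)
}

md_row <- function(cells) paste0("| ", paste(cells, collapse = " | "), " |")

md_corr_table <- function(t2) {
  pops <- c("all", stratum_levels())
  labs <- unique(t2$predictor_label)
  header <- md_row(c("Predictor", pops))
  sep <- md_row(rep("---", length(pops) + 1))
  body <- vapply(labs, function(lab) {
    vals <- vapply(pops, function(p) {
      r <- t2[t2$predictor_label == lab & t2$population_label == p, ]
      if (!nrow(r) || is.na(r$r2[1])) "-" else sprintf("%.3f", r$r2[1])
    }, "")
    md_row(c(lab, vals))
  }, "")
  c(header, sep, body)
}

md_clarke_table <- function(t3) {
  header <- md_row(c("Predictor", "Population", LETTERS[1:5]))
  sep <- md_row(rep("---", 7))
  cells <- unique(t3[, c("predictor_label", "population_label")])
  body <- vapply(seq_len(nrow(cells)), function(k) {
    sub <- t3[t3$predictor_label == cells$predictor_label[k] &
                t3$population_label == cells$population_label[k], ]
    props <- vapply(LETTERS[1:5], function(z) {
      v <- sub$proportion[sub$zone == z]
      if (!length(v) || is.na(v[1])) "-" else sprintf("%.2f", v[1])
    }, "")
    md_row(c(cells$predictor_label[k], cells$population_label[k], props))
  }, "")
  c(header, sep, body)
}

md_cv_table <- function(t4) {
  header <- md_row(c("Learner", "Features", "RMSE (95% CI)", "R2 (95% CI)",
                     "MAE (95% CI)"))
  sep <- md_row(rep("---", 5))
  body <- vapply(seq_len(nrow(t4)), function(k) {
    md_row(c(t4$learner[k], t4$feature_set[k],
             sprintf("%.1f (%.1f-%.1f)", t4$rmse_mean[k], t4$rmse_lo[k],
                     t4$rmse_hi[k]),
             sprintf("%.3f (%.3f-%.3f)", t4$r2_mean[k], t4$r2_lo[k],
                     t4$r2_hi[k]),
             sprintf("%.1f (%.1f-%.1f)", t4$mae_mean[k], t4$mae_lo[k],
                     t4$mae_hi[k])))
  }, "")
  c(header, sep, body)
}

#' Clarke Error Grid scatter plot
#'
#' Draws (reference, predicted) pairs over the canonical zone boundaries.
#'
#' @param reference_bg,predicted_bg positive glucose vectors, mg/dL.
#' @param main plot title.
#' @export
plot_error_grid <- function(reference_bg, predicted_bg,
                            main = "Clarke Error Grid") {
  lim <- c(0, max(400, reference_bg, predicted_bg))
  plot(reference_bg, predicted_bg, pch = 16, cex = 0.3,
       col = grDevices::adjustcolor("steelblue", 0.4),
       xlim = lim, ylim = lim, xlab = "Reference next BG (mg/dL)",
       ylab = "Predicted next BG (mg/dL)", main = main)
  graphics::abline(0, 1, lty = 2)
  graphics::abline(0, 1.2, col = "grey40")
  graphics::abline(0, 0.8, col = "grey40")
  graphics::segments(c(70, 0, 180, 240), c(0, 70, 70, 70),
                     c(70, 70, 180, lim[2]), c(56, 70, 70, 70),
                     col = "grey40")
  graphics::segments(c(70, 130), c(180, 0), c(290, 180), c(400, 70),
                     col = "grey40", lty = 3)
  graphics::text(c(30, 30, 350, 350), c(30, 350, 30, 160),
                 c("A", "E", "E", "D"), col = "grey30")
}

plot_error_grid_file <- function(rows, path, predictor = "ma_4h") {
  if (!predictor %in% names(rows)) predictor <- "index_bg"
  n <- nrow(rows)
  keep <- if (n > 5000) seq(1L, n, length.out = 5000) else seq_len(n)
  grDevices::png(path, width = 900, height = 900, res = 130)
  on.exit(grDevices::dev.off())
  plot_error_grid(rows$target_bg[keep], rows[[predictor]][keep],
                  main = sprintf("Clarke Error Grid: %s", predictor))
}

plot_admission_overlay_file <- function(rows, path,
                                        predictors = c("ma_4h", "rr_4")) {
  counts <- table(rows$admission_id)
  adm <- names(counts)[which.max(counts)]
  sub <- rows[rows$admission_id == adm, ]
  sub <- sub[order(sub$index_t_minutes), ]
  predictors <- intersect(predictors, names(sub))
  grDevices::png(path, width = 1100, height = 600, res = 130)
  on.exit(grDevices::dev.off())
  th <- sub$index_t_minutes / 60
  ylim <- range(sub$target_bg, unlist(sub[predictors]))
  plot(th, sub$target_bg, type = "b", pch = 16, cex = 0.6, col = "blue3",
       xlab = "Hours since admission", ylab = "BG (mg/dL)", ylim = ylim,
       main = sprintf("Admission %s: next BG vs predictors", adm))
  cols <- c("red3", "darkorange3")
  for (k in seq_along(predictors))
    graphics::lines(th, sub[[predictors[k]]], col = cols[k], lwd = 1.5)
  graphics::legend("topright", bty = "n", lwd = c(1.5, rep(1.5,
                   length(predictors))), col = c("blue3", cols),
                   legend = c("next BG", predictors))
}
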