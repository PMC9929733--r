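#' Agreement metrics between predicted and observed next BG
#'
#' `r_squared()` is the square of the Pearson product-moment correlation
#' between predictions and targets.  Note this is *not* the
#' coefficient of determination `1 - SSres/SStot`: a prediction that is any
#' exact linear function of the target (even with the wrong sign) scores 1.
#' `rmse()` is the root mean squared error and `mae()` the *median*
#' absolute error, both in mg/dL.
#'
#' @param pred,target equal-length numeric vectors.
#' @return a scalar metric value.
#' @export
#' @examples
#' r_squared(c(1, 2, 3), c(2, 4, 6))   # 1: linear invariance
#' mae(c(100, 100, 130), c(100, 100, 100))  # 0: median, not mean
r_squared <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 2L)
    contract_error("need two equal-length vectors of length >= 2")
  if (var(pred) == 0 || var(target) == 0)
    bg_error("correlation undefined: an input has zero variance",
             "bg_degenerate_error")
  cor(pred, target)^2
}

#' @rdname r_squared
#' @export
rmse <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 1L)
    contract_error("need two equal-length non-empty vectors")
  sqrt(mean((pred - target)^2))
}

#' @rdname r_squared
#' @export
mae <- function(pred, target) {
  if (length(pred) != length(target) || length(pred) < 1L)
    contract_error("need two equal-length non-empty vectors")
  median(abs(pred - target))
}

#' Qualitative band for a squared-correlation value
#'
#' `> 0.75` is `"good"`, `[0.50, 0.75]` is `"acceptable"` (boundaries
#' inclusive), `< 0.50` is `"inadequate"`.
#'
#' @param r2 numeric vector of squared correlations in `[0, 1]`.
#' @return character vector of band labels.
#' @export
classify_r2 <- function(r2) {
  stopifnot(all(is.na(r2) | (r2 >= 0 & r2 <= 1)))
  out <- rep(NA_character_, length(r2))
  out[!is.na(r2) & r2 > 0.75] <- "good"
  out[!is.na(r2) & r2 >= 0.50 & r2 <= 0.75] <- "acceptable"
  out[!is.na(r2) & r2 < 0.50] <- "inadequate"
  out
}

#' Clarke Error Grid zone assignment
#'
#' Assigns each (reference, predicted) glucose pair to one of the five
#' clinical-accuracy zones of the Clarke Error Grid: A (within 20% of the
#' reference, or both values hypoglycemic), B (benign error), C (would
#' trigger unnecessary treatment), D (dangerous failure to detect
#' hypo-/hyperglycemia), E (would confuse treatment of hypoglycemia for
#' hyperglycemia or vice versa).  The canonical 1987 piecewise boundaries
#' are evaluated with fixed precedence A, E, C, D, else B.
#'
#' @param reference_bg true next BG, mg/dL (positive).
#' @param predicted_bg predicted next BG, mg/dL (positive).
#' @return character vector of zones `"A"`..`"E"`.
#' @export
#' @examples
#' clarke_zone(c(100, 50, 250), c(100, 200, 100))  # "A" "E" "D"
clarke_zone <- function(reference_bg, predicted_bg) {
  ref <- as.numeric(reference_bg)
  pred <- as.numeric(predicted_bg)
  if (length(ref) != length(pred))
    contract_error("reference and prediction must have equal length")
  if (any(!is.finite(ref) | !is.finite(pred) | ref <= 0 | pred <= 0))
    contract_error("glucose values must be positive and finite")

  zone <- rep("B", length(ref))
  a <- (ref < 70 & pred < 70) | (abs(pred - ref) <= 0.2 * ref)
  e <- (ref <= 70 & pred >= 180) | (ref >= 180 & pred <= 70)
  cc <- (ref >= 70 & ref <= 290 & pred >= ref + 110) |
        (ref >= 130 & ref <= 180 & pred <= (7 / 5) * ref - 182)
  d <- (ref >= 240 & pred >= 70 & pred <= 180) |
       (ref <= 175 / 3 & pred >= 70 & pred <= 180) |
       (ref >= 175 / 3 & ref <= 70 & pred >= (6 / 5) * ref)
  zone[d] <- "D"
  zone[cc] <- "C"   # precedence C over D (the regions are disjoint anyway)
  zone[e] <- "E"
  zone[a] <- "A"
  zone
}

#' Clarke Error Grid zone table for one prediction vector
#'
#' @param reference_bg,predicted_bg positive glucose vectors, mg/dL.
#' @return list with `zone_counts` and `zone_props`, both named A-E.
#' @export
clarke_table <- function(reference_bg, predicted_bg) {
  z <- factor(clarke_zone(reference_bg, predicted_bg), levels = LETTERS[1:5])
  counts <- table(z)
  list(zone_counts = setNames(as.integer(counts), LETTERS[1:5]),
       zone_props = setNames(as.numeric(counts) / length(z), LETTERS[1:5]))
}

#' Score the predictor battery overall, by stratum, and by subpopulation
#'
#' Produces the two standard result tables of the analysis:
#'
#' * `correlation`: one row per predictor x population, where populations
#'   are all observations plus the four glycemic-variability strata;
#'   columns `n`, `r2` (squared Pearson), `rmse`, `mae` (median absolute
#'   error) and the qualitative `r2_band`.
#' * `clarke`: Clarke Error Grid zone proportions per predictor for the
#'   full population, admissions with type 1 diabetes, and admissions with
#'   type 2 diabetes that have basal insulin on board at the index reading.
#'
#' Cells with fewer than 2 rows, or degenerate variance, are flagged
#' (`flagged = TRUE`) and carry `NA` metrics.
#'
#' @param rows a `bg_prediction_rows` data.frame.
#' @param predictor_labels predictor columns to score (default: all
#'   battery columns present).
#' @param clarke_predictors predictor columns for the error-grid table
#'   (default: the classic comparison set, intersected with available
#'   columns).
#' @return list of class `bg_eval` with `correlation` and `clarke`
#'   data.frames.
#' @export
evaluate_grid <- function(rows,
                          predictor_labels = NULL,
                          clarke_predictors = c("ma_4h", "ma_24h", "rr_3",
                                                "rr_25", "recursive")) {
  labs <- predictor_labels %||%
    intersect(predictor_config()$labels, names(rows))
  missing <- setdiff(labs, names(rows))
  if (length(missing))
    contract_error(paste("missing predictor columns:",
                         paste(missing, collapse = ", ")))

  pops <- c("all", stratum_levels())
  cells <- expand.grid(predictor_label = labs, population_label = pops,
                       stringsAsFactors = FALSE)
  stat1 <- function(lab, pop) {
    sel <- if (pop == "all") rep(TRUE, nrow(rows)) else rows$stratum == pop
    p <- rows[[lab]][sel]; y <- rows$target_bg[sel]
    n <- length(p)
    if (n < 2L || var(p) == 0 || var(y) == 0)
      return(data.frame(n = n, r2 = NA_real_, rmse = NA_real_,
                        mae = NA_real_, r2_band = NA_character_,
                        flagged = TRUE))
    r2 <- r_squared(p, y)
    data.frame(n = n, r2 = r2, rmse = rmse(p, y), mae = mae(p, y),
               r2_band = classify_r2(r2), flagged = FALSE)
  }
  correlation <- cbind(cells, do.call(rbind, Map(
    stat1, cells$predictor_label, cells$population_label)))
  rownames(correlation) <- NULL

  clabs <- intersect(clarke_predictors, names(rows))
  cpops <- list(
    full = rep(TRUE, nrow(rows)),
    T1D = (rows$diabetes_dx %||% rep(NA, nrow(rows))) == "T1D",
    T2D_basal_insulin =
      ((rows$diabetes_dx %||% rep(NA, nrow(rows))) == "T2D") &
      ((rows$insulin_basal %||% rep(NA_real_, nrow(rows))) > 0))
  clarke <- do.call(rbind, lapply(clabs, function(lab) {
    do.call(rbind, lapply(names(cpops), function(pop) {
      sel <- cpops[[pop]] & !is.na(cpops[[pop]])
      n <- sum(sel)
      if (n == 0L)
        return(data.frame(predictor_label = lab, population_label = pop,
                          n = 0L, zone = LETTERS[1:5], count = 0L,
                          proportion = NA_real_, flagged = TRUE))
      tab <- clarke_table(rows$target_bg[sel], rows[[lab]][sel])
      data.frame(predictor_label = lab, population_label = pop, n = n,
                 zone = LETTERS[1:5], count = tab$zone_counts,
                 proportion = tab$zone_props, flagged = FALSE)
    }))
  }))
  rownames(clarke) <- NULL
  structure(list(correlation = correlation, clarke = clarke),
            class = "bg_eval")
}

#' @export
print.bg_eval <- function(x, ...) {
  cat("<bg_eval> correlation table:", nrow(x$correlation), "cells;",
      "clarke table:", nrow(x$clarke), "rows\n")
  allr <- x$correlation[x$correlation$population_label == "all", ]
  top <- allr[order(-allr$r2), ][seq_len(min(5, nrow(allr))), ]
  cat("  top predictors (all observations):\n")
  for (k in seq_len(nrow(top)))
    cat(sprintf("    %-10s r2=%.3f rmse=%.1f mae=%.1f (%s)\n",
                top$predictor_label[k], top$r2[k], top$rmse[k],
                top$mae[k], top$r2_band[k]))
  invisible(x)
}
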