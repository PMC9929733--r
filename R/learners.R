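#' Feature matrix for the learner comparison
#'
#' Model A uses exactly the time-series predictor battery (24 columns under
#' the default [predictor_config()]).  Model B appends the clinical
#' covariates — sex, age, race, diabetes diagnosis, nil-per-os status, home
#' insulin, home antihyperglycemic medication, glomerular filtration rate,
#' hydrocortisone equivalents on board, and units on board for the seven
#' insulin classes — with categorical fields one-hot encoded (reference
#' levels dropped).  Column order is deterministic.
#'
#' @param rows a `bg_prediction_rows` data.frame.
#' @param feature_set `"model_A"` or `"model_B"`.
#' @param predictor_labels time-series columns to use (default: the full
#'   default battery).
#' @return numeric matrix with labeled columns.
#' @export
make_feature_matrix <- function(rows,
                                feature_set = c("model_A", "model_B"),
                                predictor_labels = predictor_config()$labels) {
  feature_set <- match.arg(feature_set)
  missing <- setdiff(predictor_labels, names(rows))
  if (length(missing))
    bg_error(paste("prediction rows lack predictor columns:",
                   paste(missing, collapse = ", ")), "bg_schema_error")
  X <- as.matrix(as.data.frame(rows)[, predictor_labels, drop = FALSE])
  storage.mode(X) <- "double"
  if (feature_set == "model_A") return(X)

  needed <- c("age", "sex", "race", "diabetes_dx", "npo", "home_insulin",
              "home_antihyperglycemic", "gfr", "hydrocortisone_equiv",
              "insulin_basal", "insulin_combination", "insulin_concentrated",
              "insulin_intermediate", "insulin_rapid", "insulin_regular",
              "insulin_ultralong")
  missing <- setdiff(needed, names(rows))
  if (length(missing))
    bg_error(paste("model B requires covariate columns:",
                   paste(missing, collapse = ", ")), "bg_schema_error")

  onehot <- function(x, levels, prefix) {
    m <- vapply(levels[-1], function(l) as.numeric(x == l),
                numeric(length(x)))
    matrix(m, nrow = length(x), ncol = length(levels) - 1L,
           dimnames = list(NULL, paste0(prefix, "_", levels[-1])))
  }
  cov <- cbind(
    age = as.numeric(rows$age),
    onehot(rows$sex, c("female", "male"), "sex"),
    onehot(rows$race, c("white", "black", "other"), "race"),
    onehot(rows$diabetes_dx, c("none", "T1D", "T2D", "other"), "dx"),
    npo = as.numeric(rows$npo),
    home_insulin = as.numeric(rows$home_insulin),
    home_antihyperglycemic = as.numeric(rows$home_antihyperglycemic),
    gfr = as.numeric(rows$gfr),
    hydrocortisone_equiv = as.numeric(rows$hydrocortisone_equiv),
    insulin_basal = as.numeric(rows$insulin_basal),
    insulin_combination = as.numeric(rows$insulin_combination),
    insulin_concentrated = as.numeric(rows$insulin_concentrated),
    insulin_intermediate = as.numeric(rows$insulin_intermediate),
    insulin_rapid = as.numeric(rows$insulin_rapid),
    insulin_regular = as.numeric(rows$insulin_regular),
    insulin_ultralong = as.numeric(rows$insulin_ultralong))
  cbind(X, cov)
}

## ---- learner registry -----------------------------------------------------

fit_linear <- function(X, y, ...) {
  qrX <- qr(cbind(`(Intercept)` = 1, X))
  beta <- qr.coef(qrX, y)
  beta[is.na(beta)] <- 0   # aliased columns contribute nothing
  list(beta = beta)
}
predict_linear <- function(model, X) {
  drop(cbind(1, X) %*% model$beta)
}

# PLS1 via NIPALS on standardized features.
fit_pls_ncomp <- function(X, y, ncomp) {
  mx <- colMeans(X); sx <- apply(X, 2, sd); sx[sx == 0] <- 1
  X0 <- sweep(sweep(X, 2, mx), 2, sx, "/")
  my <- mean(y); y0 <- y - my
  p <- ncol(X0); ncomp <- min(ncomp, p)
  W <- P <- matrix(0, p, ncomp); Q <- numeric(ncomp)
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(X0, y0))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    tt <- drop(X0 %*% w)
    tsq <- sum(tt^2)
    pp <- drop(crossprod(X0, tt)) / tsq
    qq <- sum(y0 * tt) / tsq
    X0 <- X0 - tcrossprod(tt, pp)
    y0 <- y0 - qq * tt
    W[, a] <- w; P[, a] <- pp; Q[a] <- qq
  }
  if (ncomp == 0L) return(list(mx = mx, sx = sx, my = my, B = NULL))
  W <- W[, seq_len(ncomp), drop = FALSE]
  P <- P[, seq_len(ncomp), drop = FALSE]
  Q <- Q[seq_len(ncomp)]
  B <- W %*% solve(crossprod(P, W), Q)
  list(mx = mx, sx = sx, my = my, B = drop(B))
}
predict_pls <- function(model, X) {
  if (is.null(model$B)) return(rep(model$my, nrow(X)))
  X0 <- sweep(sweep(X, 2, model$mx), 2, model$sx, "/")
  model$my + drop(X0 %*% model$B)
}

fit_knn_k <- function(X, y, k) {
  mx <- colMeans(X); sx <- apply(X, 2, sd); sx[sx == 0] <- 1
  list(X = sweep(sweep(X, 2, mx), 2, sx, "/"), y = y,
       mx = mx, sx = sx, k = k)
}
predict_knn <- function(model, X) {
  X0 <- sweep(sweep(X, 2, model$mx), 2, model$sx, "/")
  drop(knn_mean_cpp(model$X, model$y, X0,
                    as.integer(min(model$k, nrow(model$X)))))
}

# k-NN tuning shares one distance computation across the whole k grid.
tune_knn <- function(X, y, grid) {
  n <- nrow(X)
  hold <- sample.int(n, max(1L, floor(n / 5)))
  m <- fit_knn_k(X[-hold, , drop = FALSE], y[-hold], max(grid))
  X0 <- sweep(sweep(X[hold, , drop = FALSE], 2, m$mx), 2, m$sx, "/")
  preds <- knn_mean_cpp(m$X, m$y, X0, as.integer(grid))
  scores <- vapply(seq_along(grid), function(j)
    rmse(preds[, j], y[hold]), 0)
  grid[which.min(scores)]
}

fit_forest <- function(X, y, n_trees = 100L, ...) {
  forest <- rf_fit_cpp(X, y, ntree = as.integer(n_trees),
                       mtry = max(1L, floor(ncol(X) / 3)),
                       min_leaf = 5L, min_split = 10L, max_depth = 30L)
  list(forest = forest)
}
predict_forest <- function(model, X) rf_predict_cpp(model$forest, X)

# Inner-resampling tuner: single 80/20 split of the training fold, smallest
# held-out RMSE wins (ties to the first/smallest value in the grid).
tune_by_split <- function(X, y, grid, fit_fun, predict_fun) {
  n <- nrow(X)
  hold <- sample.int(n, max(1L, floor(n / 5)))
  scores <- vapply(grid, function(g) {
    m <- fit_fun(X[-hold, , drop = FALSE], y[-hold], g)
    rmse(predict_fun(m, X[hold, , drop = FALSE]), y[hold])
  }, 0)
  grid[which.min(scores)]
}

#' Available regression learners
#'
#' Returns the pluggable learner registry used by [run_cv_experiment()]:
#' `linear` (ordinary least squares), `partial_least_squares` (NIPALS,
#' components tuned over 2/5/10 by inner resampling),
#' `k_nearest_neighbors` (standardized Euclidean, k tuned over 5/7/9),
#' and `random_forest` (bagged regression trees, 100 trees, mtry = p/3).
#' The optional Cubist-style rule ensemble has no faithful implementation
#' in this environment and is not registered; [run_cv_experiment()]
#' records the substitution in its metadata when it is requested.
#'
#' @return named list of learner definitions (`fit(X, y)` returning a
#'   model with a `hyper` note, and `predict(model, X)`).
#' @export
learner_registry <- function() {
  list(
    linear = list(
      fit = function(X, y) c(fit_linear(X, y), list(hyper = "none")),
      predict = predict_linear),
    partial_least_squares = list(
      fit = function(X, y) {
        nc <- tune_by_split(X, y, c(2L, 5L, 10L), fit_pls_ncomp, predict_pls)
        c(fit_pls_ncomp(X, y, nc), list(hyper = paste0("ncomp=", nc)))
      },
      predict = predict_pls),
    k_nearest_neighbors = list(
      fit = function(X, y) {
        k <- tune_knn(X, y, c(5L, 7L, 9L))
        c(fit_knn_k(X, y, k), list(hyper = paste0("k=", k)))
      },
      predict = predict_knn),
    random_forest = list(
      fit = function(X, y)
        c(fit_forest(X, y), list(hyper = "n_trees=100,mtry=p/3")),
      predict = predict_forest))
}
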