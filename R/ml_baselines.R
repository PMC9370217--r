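## Default hyperparameter grids for the non-linear baselines. Small on
## purpose: the comparison protocol (shared folds, CV-R2 scoring), not any
## particular grid, is the contract; grids are user-overridable.
.default_grid <- function(method, p) {
  switch(method,
    kNN = expand.grid(k = c(3, 5, 7, 9)),
    RF  = expand.grid(mtry = unique(pmax(1, round(c(p / 3, p / 2, p)))),
                      ntree = 500),
    SVM = expand.grid(cost = c(1, 10, 100), gamma = c(0.01, 0.1, 1)),
    MLP = expand.grid(size = c(3, 5, 8), decay = c(0.01, 0.1)),
    GB  = expand.grid(nrounds = c(100, 300), eta = c(0.1, 0.3),
                      max_depth = c(2, 4)),
    stop("unknown method: ", method, call. = FALSE)
  )
}

.fit_one <- function(method, params, x, y, seed) {
  withr::with_seed(seed, switch(method,
    kNN = caret::knnreg(x, y, k = params$k),
    RF  = randomForest::randomForest(x, y, mtry = params$mtry,
                                     ntree = params$ntree),
    SVM = e1071::svm(x, y, cost = params$cost, gamma = params$gamma,
                     type = "eps-regression", kernel = "radial"),
    MLP = nnet::nnet(x, y, size = params$size, decay = params$decay,
                     linout = TRUE, maxit = 500, trace = FALSE),
    GB  = xgboost::xgboost(as.matrix(x), y,
                           nrounds = params$nrounds,
                           learning_rate = params$eta,
                           max_depth = params$max_depth,
                           objective = "reg:squarederror",
                           nthreads = 1, verbosity = 0)
  ))
}

.predict_one <- function(method, fit, x) {
  switch(method,
    kNN = stats::predict(fit, x),
    RF  = stats::predict(fit, x),
    SVM = stats::predict(fit, x),
    MLP = drop(stats::predict(fit, x)),
    GB  = stats::predict(fit, as.matrix(x))
  )
}

#' Tune and fit a non-linear baseline regressor
#'
#' Grid search for one of five machine-learning regressors on a fixed,
#' already-selected feature subset, scored by the mean out-of-fold
#' R-squared over a k-fold cross-validation whose fold assignment is
#' derived from `rng_seed` (so all methods compared within one run share
#' the same folds). The best setting is refit on the full training set.
#' Deterministic given the seed.
#'
#' @param features data frame of predictor columns.
#' @param y numeric response.
#' @param method one of `"kNN"`, `"RF"`, `"SVM"`, `"MLP"`, `"GB"`.
#' @param grid data frame of hyperparameter combinations; `NULL` for the
#'   documented defaults.
#' @param cv_folds number of folds (default 5).
#' @param rng_seed seed for fold assignment and stochastic fitters.
#' @return An `ml_baseline` list: `method`, `best_params`, `fit`,
#'   `q2_cv` (mean CV R-squared of the best setting), `cv_table`.
#' @export
tune_and_fit <- function(features, y, method, grid = NULL, cv_folds = 5,
                         rng_seed = 1) {
  if (!method %in% c("kNN", "RF", "SVM", "MLP", "GB")) {
    stop("unknown method: ", method, call. = FALSE)
  }
  x <- as.data.frame(features)
  if (is.null(grid)) grid <- .default_grid(method, ncol(x))
  folds <- .fold_assignment(length(y), cv_folds, rng_seed)
  cv_scores <- vapply(seq_len(nrow(grid)), function(g) {
    r2s <- vapply(seq_len(cv_folds), function(f) {
      tr <- folds != f
      fit <- .fit_one(method, grid[g, , drop = FALSE],
                      x[tr, , drop = FALSE], y[tr], rng_seed + f)
      pred <- .predict_one(method, fit, x[!tr, , drop = FALSE])
      1 - sum((y[!tr] - pred)^2) / sum((y[!tr] - mean(y[tr]))^2)
    }, numeric(1))
    mean(r2s)
  }, numeric(1))
  best <- which.max(cv_scores)  # first grid row wins ties
  fit <- .fit_one(method, grid[best, , drop = FALSE], x, y, rng_seed)
  structure(list(method = method,
                 best_params = grid[best, , drop = FALSE],
                 fit = fit, q2_cv = cv_scores[best],
                 cv_table = cbind(grid, cv_r2 = cv_scores),
                 feature_names = names(x)),
            class = "ml_baseline")
}

#' @export
predict.ml_baseline <- function(object, newdata, ...) {
  x <- as.data.frame(newdata)[, object$feature_names, drop = FALSE]
  .predict_one(object$method, object$fit, x)
}

#' @export
print.ml_baseline <- function(x, ...) {
  cat(sprintf("ml_baseline [%s]: CV R2 = %.3f; best: %s\n", x$method, x$q2_cv,
              paste(names(x$best_params), unlist(x$best_params),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Compare several baseline methods on one training set
#'
#' Runs [tune_and_fit()] for each requested method with a shared fold
#' assignment and summarizes internal and external predictivity in one
#' table.
#'
#' @param train_features,train_y training data.
#' @param test_sets named list of `list(features =, y =)` external sets.
#' @param methods methods to compare.
#' @inheritParams tune_and_fit
#' @return Data frame with one row per method: `q2_cv` plus an
#'   `r2_pred_<set>` column per external set.
#' @export
baseline_table <- function(train_features, train_y, test_sets = list(),
                           methods = c("kNN", "RF", "SVM", "MLP", "GB"),
                           cv_folds = 5, rng_seed = 1) {
  rows <- lapply(methods, function(m) {
    fit <- tune_and_fit(train_features, train_y, m, cv_folds = cv_folds,
                        rng_seed = rng_seed)
    row <- data.frame(method = m, q2_cv = fit$q2_cv)
    for (nm in names(test_sets)) {
      pred <- predict(fit, test_sets[[nm]]$features)
      row[[paste0("r2_pred_", nm)]] <-
        r2_pred(test_sets[[nm]]$y, pred, mean(train_y))
    }
    row
  })
  do.call(rbind, rows)
}
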