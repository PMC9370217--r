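#' Ordinary least squares fit with full statistics
#'
#' Fits `y ~ 1 + features` by QR-based least squares and returns the
#' coefficients with their standard errors plus the usual fit statistics:
#' R-squared, adjusted R-squared, the F statistic, the training size and
#' the data-points-per-variable ratio `rho = N_tr / p`. For a constant
#' response R-squared is reported as 0 by convention.
#'
#' @param features data frame or matrix of predictor columns (no intercept).
#' @param y numeric response vector.
#' @return A `linear_model` object.
#' @export
fit_ols <- function(features, y) {
  x <- as.matrix(as.data.frame(features))
  n <- nrow(x); p <- ncol(x)
  if (n < p + 2) stop("need at least p + 2 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  X <- cbind(`(Intercept)` = 1, x)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dep <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("singular design matrix; linearly dependent column(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qrx, y)
  fitted <- drop(X %*% coefs)
  resid <- y - fitted
  df_res <- n - p - 1
  rss <- sum(resid^2)
  tss <- sum((y - mean(y))^2)
  sigma2 <- rss / df_res
  xtx_inv <- chol2inv(qr.R(qrx)[seq_len(ncol(X)), , drop = FALSE])
  # undo the pivot so rows/cols of xtx_inv match X's column order
  unpivot <- order(qrx$pivot)
  xtx_inv <- xtx_inv[unpivot, unpivot, drop = FALSE]
  se <- sqrt(diag(xtx_inv) * sigma2)
  names(se) <- colnames(X)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  r2_adj <- if (tss > 0 && df_res > 0) 1 - (1 - r2) * (n - 1) / df_res else 0
  f_stat <- if (p > 0 && rss > 0) (tss - rss) / p / sigma2 else Inf
  hat <- rowSums((X %*% xtx_inv) * X)
  structure(list(
    feature_names = colnames(x),
    intercept = unname(coefs[1]),
    coefficients = coefs[-1],
    se = se,
    r2 = r2, r2_adj = r2_adj, f_stat = f_stat,
    n_tr = n, rho = if (p > 0) n / p else Inf,
    sigma = sqrt(sigma2), df_residual = df_res,
    fitted = fitted, residuals = resid, hat = hat,
    xtx_inv = xtx_inv
  ), class = "linear_model")
}

#' @export
print.linear_model <- function(x, digits = 4, ...) {
  cat(sprintf("linear_model: %d feature(s), N_tr = %d\n",
              length(x$feature_names), x$n_tr))
  tab <- data.frame(
    coefficient = signif(c(x$intercept, x$coefficients), digits),
    std_error = signif(x$se, digits),
    row.names = c("(Intercept)", x$feature_names)
  )
  print(tab)
  cat(sprintf("R2 = %.4f, R2_adj = %.4f, F = %.2f, rho = %.1f\n",
              x$r2, x$r2_adj, x$f_stat, x$rho))
  invisible(x)
}

#' Predict from a fitted linear model
#'
#' @param object a `linear_model`.
#' @param newdata data frame containing every model feature as a column.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.linear_model <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  missing_cols <- setdiff(object$feature_names, names(newdata))
  if (length(missing_cols) > 0) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(object$feature_names) == 0) {
    return(rep(object$intercept, nrow(newdata)))
  }
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  drop(object$intercept + x %*% object$coefficients)
}

## LOO-deleted residuals via the hat-matrix identity e_i / (1 - h_i);
## exact for OLS, equivalent to n literal refits.
.loo_residuals <- function(features, y) {
  if (is.null(features) || ncol(as.data.frame(features)) == 0) {
    n <- length(y)
    resid <- y - mean(y)
    return(resid / (1 - 1 / n))
  }
  fit <- fit_ols(features, y)
  fit$residuals / (1 - fit$hat)
}

.mae_loo <- function(features, y) mean(abs(.loo_residuals(features, y)))

## Deterministic k-fold assignment derived from a seed; RNG state restored.
.fold_assignment <- function(n, k, seed) {
  withr::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
}

.score_model <- function(features, y, scoring, folds) {
  x <- as.data.frame(features)
  if (scoring %in% c("R2", "NMAE", "NMPD")) {
    fit <- fit_ols(x, y)
    switch(scoring,
      R2 = fit$r2,
      NMAE = -mean(abs(fit$residuals)),
      NMPD = {
        if (any(y <= 0)) stop("NMPD scoring requires positive responses",
                              call. = FALSE)
        mu <- pmax(fit$fitted, 1e-6)
        -mean(2 * (y * log(y / mu) - (y - mu)))
      }
    )
  } else {  # R2_cv5 / R2_cv10 : mean out-of-fold R2
    k <- max(folds)
    r2s <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- fit_ols(x[tr, , drop = FALSE], y[tr])
      pred <- predict(fit, x[!tr, , drop = FALSE])
      obs <- y[!tr]
      1 - sum((obs - pred)^2) / sum((obs - mean(y[tr]))^2)
    }, numeric(1))
    mean(r2s)
  }
}

#' Sequential forward selection of linear-model descriptors
#'
#' Greedy forward selection over the candidate columns of a (filtered)
#' feature matrix. At each step every remaining candidate is scored by the
#' chosen criterion when added to the incumbent model, and the best
#' candidate (ties broken by lowest column index) is provisionally added.
#' The addition is kept only if it reduces the leave-one-out
#' cross-validation mean absolute error by at least `mae_reduction`
#' (default 5%) relative to the incumbent: `MAE_LOO(new) <=
#' (1 - mae_reduction) * MAE_LOO(incumbent)`. Selection stops at the first
#' rejected addition. This error-reduction policy fixes the number of
#' descriptors without a user-chosen model size.
#'
#' Scoring criteria: `"R2"` (training determination coefficient),
#' `"NMAE"` (negative mean absolute error), `"NMPD"` (negative mean
#' Poisson deviance; responses must be positive, predictions are clipped
#' at `1e-6`), `"R2_cv5"`/`"R2_cv10"` (mean out-of-fold R-squared over a
#' fixed 5- or 10-fold assignment derived from `cv_seed`).
#'
#' @param features a filtered `feature_matrix` (see [filter_features()]).
#' @param y numeric response vector.
#' @param scoring one of `"R2"`, `"NMAE"`, `"NMPD"`, `"R2_cv5"`, `"R2_cv10"`.
#' @param mae_reduction required relative MAE_LOO reduction per step.
#' @param cv_seed seed for the cross-validation fold assignment.
#' @return A `linear_model` with attributes `trace` (one row per attempted
#'   step) and, when no first feature qualifies, `intercept_only = TRUE`.
#' @export
sfs_select <- function(features, y,
                       scoring = c("R2", "NMAE", "NMPD", "R2_cv5", "R2_cv10"),
                       mae_reduction = 0.05, cv_seed = 1) {
  scoring <- match.arg(scoring)
  x <- as.data.frame(features)
  candidates <- names(x)
  folds <- if (scoring %in% c("R2_cv5", "R2_cv10")) {
    .fold_assignment(length(y), if (scoring == "R2_cv5") 5 else 10, cv_seed)
  } else NULL
  selected <- character(0)
  mae_inc <- .mae_loo(NULL, y)
  trace <- list()
  repeat {
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    scores <- vapply(remaining, function(f) {
      .score_model(x[, c(selected, f), drop = FALSE], y, scoring, folds)
    }, numeric(1))
    best <- remaining[which.max(scores)]  # which.max: lowest index on ties
    mae_new <- .mae_loo(x[, c(selected, best), drop = FALSE], y)
    accepted <- mae_new <= (1 - mae_reduction) * mae_inc
    trace[[length(trace) + 1L]] <- data.frame(
      step = length(trace) + 1L, feature = best,
      score = max(scores), mae_loo_before = mae_inc,
      mae_loo_after = mae_new, accepted = accepted
    )
    if (!accepted) break
    selected <- c(selected, best)
    mae_inc <- mae_new
  }
  if (length(selected) == 0) {
    warning("no candidate reduced MAE_LOO by the required margin; ",
            "returning intercept-only model")
    model <- structure(list(
      feature_names = character(0), intercept = mean(y),
      coefficients = stats::setNames(numeric(0), character(0)),
      se = c(`(Intercept)` = stats::sd(y) / sqrt(length(y))),
      r2 = 0, r2_adj = 0, f_stat = NA_real_,
      n_tr = length(y), rho = Inf,
      sigma = stats::sd(y), df_residual = length(y) - 1,
      fitted = rep(mean(y), length(y)), residuals = y - mean(y),
      hat = rep(1 / length(y), length(y)), xtx_inv = NULL
    ), class = "linear_model")
    attr(model, "intercept_only") <- TRUE
  } else {
    model <- fit_ols(x[, selected, drop = FALSE], y)
  }
  attr(model, "trace") <- do.call(rbind, trace)
  attr(model, "scoring") <- scoring
  model
}

#' Serialize / deserialize a linear model as JSON
#'
#' The JSON schema stores feature names, intercept and coefficients with
#' standard errors, fit statistics, the selection trace (if any) and the
#' package version. `read_model()` restores a `linear_model` usable with
#' [predict.linear_model()] (training-data-dependent diagnostics such as
#' residuals are not serialized).
#'
#' @param model a `linear_model`.
#' @param path JSON file path.
#' @export
write_model <- function(model, path) {
  payload <- list(
    feature_names = model$feature_names,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    se = as.list(model$se),
    stats = list(r2 = model$r2, r2_adj = model$r2_adj, f_stat = model$f_stat,
                 n_tr = model$n_tr, rho = model$rho),
    trace = attr(model, "trace"),
    version = as.character(utils::packageVersion("mixqspr"))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_model
#' @return `read_model()` returns a `linear_model`.
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  fn <- as.character(payload$feature_names)
  coefs <- stats::setNames(as.numeric(unlist(payload$coefficients)),
                           names(payload$coefficients))[fn]
  structure(list(
    feature_names = fn,
    intercept = as.numeric(payload$intercept),
    coefficients = coefs,
    se = stats::setNames(as.numeric(unlist(payload$se)), names(payload$se)),
    r2 = payload$stats$r2, r2_adj = payload$stats$r2_adj,
    f_stat = payload$stats$f_stat, n_tr = payload$stats$n_tr,
    rho = payload$stats$rho,
    sigma = NA_real_, df_residual = NA_integer_,
    fitted = NULL, residuals = NULL, hat = NULL, xtx_inv = NULL
  ), class = "linear_model")
}
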