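#' Leave-one-out cross-validation statistics
#'
#' Computes `Q2_LOO = 1 - PRESS / sum((y - mean(y))^2)` and
#' `MAE_LOO = mean(|y_i - yhat_(-i)|)` for a fixed feature subset, using
#' the exact hat-matrix identity `e_i / (1 - h_i)` for the deleted
#' residuals (equivalent to refitting N times, but O(1) refits).
#'
#' @param features feature matrix / data frame containing `model_features`.
#' @param y numeric response.
#' @param model_features character vector of column names to use; `NULL` or
#'   empty for an intercept-only model.
#' @return List with elements `q2_loo`, `mae_loo`.
#' @export
q2_mae_loo <- function(features, y, model_features = NULL) {
  x <- if (length(model_features) > 0) {
    as.data.frame(features)[, model_features, drop = FALSE]
  } else NULL
  e_loo <- .loo_residuals(x, y)
  press <- sum(e_loo^2)
  tss <- sum((y - mean(y))^2)
  list(q2_loo = 1 - press / tss, mae_loo = mean(abs(e_loo)))
}

#' Leave-chemical-out cross-validation statistics
#'
#' For every unique chemical in the training data (union of the HBA and
#' HBD roles), all records containing it are removed, the coefficients are
#' refit on the remainder with the same feature subset, and the removed
#' records are predicted. All held-out predictions are pooled (a record
#' contributes once per chemical it contains) and `Q2_LCO`/`MAE_LCO` are
#' computed on the pooled vector, with the total sum of squares taken
#' about the pooled observed mean. Chemicals whose removal leaves too few
#' records to refit are skipped and reported.
#'
#' @param dataset the training [mixture_dataset()] (row-aligned with
#'   `features` and `y`).
#' @param features feature matrix for the training rows.
#' @param y training response vector.
#' @param model_features character vector of model columns.
#' @return List with `q2_lco`, `mae_lco`, `n_chemicals`, `skipped`
#'   (chemicals that could not be held out), and the pooled
#'   `predictions` data frame.
#' @export
q2_mae_lco <- function(dataset, features, y, model_features) {
  x <- as.data.frame(features)[, model_features, drop = FALSE]
  p <- length(model_features)
  chems <- unique(c(dataset$comp1_id, dataset$comp2_id))
  obs_pool <- numeric(0); pred_pool <- numeric(0)
  chem_pool <- character(0); id_pool <- character(0)
  skipped <- character(0)
  for (ch in chems) {
    held <- dataset$comp1_id == ch | dataset$comp2_id == ch
    if (sum(!held) < p + 2 || sum(held) == 0) {
      skipped <- c(skipped, ch)
      next
    }
    fit <- tryCatch(
      if (p > 0) fit_ols(x[!held, , drop = FALSE], y[!held]) else NULL,
      error = function(e) NULL)
    if (p > 0 && is.null(fit)) { skipped <- c(skipped, ch); next }
    pred <- if (p > 0) predict(fit, x[held, , drop = FALSE])
            else rep(mean(y[!held]), sum(held))
    obs_pool <- c(obs_pool, y[held])
    pred_pool <- c(pred_pool, pred)
    chem_pool <- c(chem_pool, rep(ch, sum(held)))
    id_pool <- c(id_pool, dataset$record_id[held])
  }
  if (length(skipped) > 0) {
    warning("leave-chemical-out skipped chemical(s): ",
            paste(skipped, collapse = ", "))
  }
  resid <- obs_pool - pred_pool
  tss <- sum((obs_pool - mean(obs_pool))^2)
  list(q2_lco = 1 - sum(resid^2) / tss,
       mae_lco = mean(abs(resid)),
       n_chemicals = length(chems) - length(skipped),
       skipped = skipped,
       predictions = data.frame(record_id = id_pool, chemical = chem_pool,
                                observed = obs_pool, predicted = pred_pool))
}

#' External-prediction determination coefficient
#'
#' `R2_Pred = 1 - sum((obs - pred)^2) / sum((obs - train_mean)^2)`, the
#' variance explained for external prediction relative to the training-set
#' mean of the response.
#'
#' @param y_obs,y_pred observed and predicted responses (equal length).
#' @param train_mean mean response of the training set.
#' @return Scalar `R2_Pred` (<= 1; can be negative).
#' @export
r2_pred <- function(y_obs, y_pred, train_mean) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) > 0)
  denom <- sum((y_obs - train_mean)^2)
  if (denom == 0) stop("undefined R2_Pred: zero denominator", call. = FALSE)
  1 - sum((y_obs - y_pred)^2) / denom
}

#' Absolute average relative deviation
#'
#' `%AARD = (100 / N) * sum(|pred - obs| / |obs|)`; the per-record signed
#' analogue `%RD = 100 * (pred - obs) / obs` is returned alongside.
#'
#' @param y_obs,y_pred observed and predicted responses; `y_obs` must be
#'   non-zero.
#' @return List with scalar `aard` (percent) and vector `rd` (percent).
#' @export
aard <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) > 0)
  if (any(y_obs == 0)) stop("zero observed value in %AARD", call. = FALSE)
  rd <- 100 * (y_pred - y_obs) / y_obs
  list(aard = mean(abs(y_pred - y_obs) / abs(y_obs)) * 100, rd = rd)
}

#' Scaled rm-squared external-validation metrics
#'
#' Both vectors are min-max scaled to `[0, 1]`; `r2` is the squared
#' Pearson correlation (free intercept) and `r0^2` / `r0'^2` are the
#' determination coefficients of the least-squares lines through the
#' origin, regressing scaled observed on scaled predicted and vice versa:
#' `r0^2 = 1 - sum((u - k v)^2) / sum((u - mean(u))^2)` with
#' `k = sum(u v) / sum(v^2)`. Then
#' `rm2 = r2 * (1 - sqrt(r2 - r0^2))` and `rm2' = r2 * (1 - sqrt(r2 -
#' r0'^2))`; the square-root arguments are clamped at zero against
#' numerical underflow.
#'
#' @param y_obs,y_pred observed and predicted responses (>= 3 points,
#'   non-constant).
#' @return List with `rm2`, `rm2_prime`, `average`, `delta`.
#' @export
rm2_metrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 3)
  if (stats::sd(y_obs) == 0 || stats::sd(y_pred) == 0) {
    stop("rm2 metrics undefined for constant vectors", call. = FALSE)
  }
  scale01 <- function(v) (v - min(v)) / (max(v) - min(v))
  u <- scale01(y_obs); v <- scale01(y_pred)
  r2 <- stats::cor(u, v)^2
  r02 <- function(a, b) {  # regression of a on b through the origin
    k <- sum(a * b) / sum(b^2)
    1 - sum((a - k * b)^2) / sum((a - mean(a))^2)
  }
  rm2 <- r2 * (1 - sqrt(max(0, r2 - r02(u, v))))
  rm2p <- r2 * (1 - sqrt(max(0, r2 - r02(v, u))))
  list(rm2 = rm2, rm2_prime = rm2p,
       average = (rm2 + rm2p) / 2, delta = abs(rm2 - rm2p))
}

#' Y-randomization (response scrambling) check
#'
#' Refits the model `n_runs` times with the response vector randomly
#' permuted while keeping the same feature subset, and summarizes the
#' separation between the true model and the chance models by
#' `cRp2 = R * sqrt(R^2 - mean(Rr^2))` where `R` is the correlation
#' coefficient of the original model and `Rr^2` the determination
#' coefficients of the randomized refits (clamped at zero if negative).
#' Values near one indicate the model is not a chance correlation.
#'
#' @param features feature matrix containing `model_features`.
#' @param y response vector.
#' @param model_features character vector of model columns.
#' @param n_runs number of permutations (>= 1; default 1000).
#' @param rng_seed seed making the permutation sequence reproducible.
#' @return A `randomization_report` list: `n_runs`, `r` (original model
#'   correlation), `r2`, `mean_r2_random`, `crp2`, and the vector
#'   `r2_random`.
#' @export
y_randomization <- function(features, y, model_features, n_runs = 1000,
                            rng_seed = 1) {
  if (n_runs < 1) stop("n_runs must be >= 1", call. = FALSE)
  x <- as.data.frame(features)[, model_features, drop = FALSE]
  fit <- fit_ols(x, y)
  r2s <- withr::with_seed(rng_seed, {
    vapply(seq_len(n_runs), function(i) fit_ols(x, sample(y))$r2, numeric(1))
  })
  crp2 <- fit$r2 - mean(r2s)
  crp2 <- if (crp2 <= 0) 0 else sqrt(fit$r2) * sqrt(crp2)
  structure(list(n_runs = n_runs, r = sqrt(fit$r2), r2 = fit$r2,
                 mean_r2_random = mean(r2s), crp2 = crp2, r2_random = r2s),
            class = "randomization_report")
}

#' @export
print.randomization_report <- function(x, ...) {
  cat(sprintf("Y-randomization: %d runs, R2 = %.3f, mean randomized R2 = %.3f, cRp2 = %.3f\n",
              x$n_runs, x$r2, x$mean_r2_random, x$crp2))
  invisible(x)
}

#' Leverage-based applicability domain (Williams plot data)
#'
#' Leverages are `h_i = x_i' (X'X)^-1 x_i` with `x` augmented by the
#' intercept and `X` the training design; external rows are evaluated with
#' the training `(X'X)^-1`. The warning leverage is `h* = 3 (p + 1) /
#' N_tr`. Standardized residuals are raw residuals divided by the standard
#' deviation of the training residuals. Records with `h > h*` are flagged
#' structural outliers; records with `|standardized residual| > 3` are
#' response outliers.
#'
#' @param model a fitted `linear_model` (fitted on the training rows).
#' @param train_features,train_y training feature matrix and response.
#' @param ... further named sets, each a `list(features =, y =)`.
#' @return An `ad_report`: data frame with columns `set`, `record_id`,
#'   `leverage`, `std_residual`, `structural_outlier`, `response_outlier`;
#'   attribute `h_star`.
#' @export
williams <- function(model, train_features, train_y, ...) {
  fn <- model$feature_names
  xtr <- as.matrix(as.data.frame(train_features)[, fn, drop = FALSE])
  Xtr <- cbind(1, xtr)
  xtx <- crossprod(Xtr)
  xtx_inv <- tryCatch(solve(xtx),
                      error = function(e) stop("singular X'X", call. = FALSE))
  p1 <- length(fn) + 1
  h_star <- 3 * p1 / nrow(Xtr)
  res_tr <- train_y - predict(model, as.data.frame(train_features))
  s <- stats::sd(res_tr)
  one_set <- function(feats, yy, label) {
    xm <- as.matrix(as.data.frame(feats)[, fn, drop = FALSE])
    Xm <- cbind(1, xm)
    h <- rowSums((Xm %*% xtx_inv) * Xm)
    res <- yy - predict(model, as.data.frame(feats))
    ids <- rownames(as.data.frame(feats))
    if (is.null(ids)) ids <- as.character(seq_len(nrow(Xm)))
    data.frame(set = label, record_id = ids, leverage = h,
               std_residual = res / s,
               structural_outlier = h > h_star,
               response_outlier = abs(res / s) > 3,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  out <- one_set(train_features, train_y, "train")
  extra <- list(...)
  for (nm in names(extra)) {
    out <- rbind(out, one_set(extra[[nm]]$features, extra[[nm]]$y, nm))
  }
  structure(out, h_star = h_star, class = c("ad_report", "data.frame"))
}

#' Full validation report for a fitted model and split
#'
#' Convenience wrapper assembling the metric battery for a (model, split)
#' pair: training LOO and leave-chemical-out statistics, external
#' `R2_Pred`/MAE/%AARD for the test (and optionally external validation)
#' set, and rm-squared metrics per set.
#'
#' @param model a `linear_model` fitted on the training rows.
#' @param train_dataset training [mixture_dataset()].
#' @param train_features,train_y training features and response.
#' @param test_features,test_y test-set features and response.
#' @param ext_features,ext_y optional external-validation features/response.
#' @return A `validation_report` list.
#' @export
validation_report <- function(model, train_dataset, train_features, train_y,
                              test_features, test_y,
                              ext_features = NULL, ext_y = NULL) {
  fn <- model$feature_names
  loo <- q2_mae_loo(train_features, train_y, fn)
  lco <- suppressWarnings(
    q2_mae_lco(train_dataset, train_features, train_y, fn))
  tmean <- mean(train_y)
  pred_tr <- predict(model, as.data.frame(train_features))
  pred_ts <- predict(model, as.data.frame(test_features))
  rep <- list(
    q2_loo = loo$q2_loo, mae_loo = loo$mae_loo,
    q2_lco = lco$q2_lco, mae_lco = lco$mae_lco,
    lco_skipped = lco$skipped,
    train = list(aard = aard(train_y, pred_tr)$aard,
                 rm2 = rm2_metrics(train_y, .loo_predictions(train_features, train_y, fn))),
    test = list(r2_pred = r2_pred(test_y, pred_ts, tmean),
                mae = mean(abs(test_y - pred_ts)),
                aard = aard(test_y, pred_ts)$aard,
                rm2 = rm2_metrics(test_y, pred_ts))
  )
  if (!is.null(ext_features)) {
    pred_ex <- predict(model, as.data.frame(ext_features))
    rep$external <- list(r2_pred = r2_pred(ext_y, pred_ex, tmean),
                         mae = mean(abs(ext_y - pred_ex)),
                         aard = aard(ext_y, pred_ex)$aard,
                         rm2 = rm2_metrics(ext_y, pred_ex))
  }
  structure(rep, class = "validation_report")
}

.loo_predictions <- function(features, y, model_features) {
  x <- if (length(model_features) > 0) {
    as.data.frame(features)[, model_features, drop = FALSE]
  } else NULL
  y - .loo_residuals(x, y)
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Q2_LOO = %.3f, MAE_LOO = %.3f | Q2_LCO = %.3f, MAE_LCO = %.3f\n",
              x$q2_loo, x$mae_loo, x$q2_lco, x$mae_lco))
  cat(sprintf("test: R2_Pred = %.3f, MAE = %.3f, %%AARD = %.3f\n",
              x$test$r2_pred, x$test$mae, x$test$aard))
  if (!is.null(x$external)) {
    cat(sprintf("external: R2_Pred = %.3f, MAE = %.3f, %%AARD = %.3f\n",
                x$external$r2_pred, x$external$mae, x$external$aard))
  }
  invisible(x)
}
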