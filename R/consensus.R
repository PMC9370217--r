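#' Consensus configuration
#'
#' @param strategy one of `"CM0"` (plain average over all members),
#'   `"CM1"` (average over qualified members), `"CM2"` (weighted average
#'   over qualified members, weights proportional to the reciprocal of the
#'   member's mean absolute error over the `k` nearest training records),
#'   `"CM3"` (per-record single best member by that neighborhood error).
#' @param k neighborhood size for the per-record error estimate (>= 1).
#' @return A `consensus_config` list.
#' @export
consensus_config <- function(strategy = c("CM0", "CM1", "CM2", "CM3"), k = 10) {
  strategy <- match.arg(strategy)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  structure(list(strategy = strategy, k = as.integer(k)),
            class = "consensus_config")
}

#' Bundle a model with its training context for consensus prediction
#'
#' @param model a fitted `linear_model`.
#' @param train_features,train_y the features and response the model was
#'   trained on (used for qualification and neighborhood error estimates).
#' @return A `consensus_member` list.
#' @export
consensus_member <- function(model, train_features, train_y) {
  structure(list(model = model,
                 train_features = as.data.frame(train_features),
                 train_y = train_y),
            class = "consensus_member")
}

## Per-member precomputation: training leverage machinery for
## qualification (h <= h*) and standardized feature space + absolute
## training residuals for neighborhood error estimates.
.member_context <- function(member) {
  fn <- member$model$feature_names
  xtr <- as.matrix(member$train_features[, fn, drop = FALSE])
  Xtr <- cbind(1, xtr)
  xtx_inv <- solve(crossprod(Xtr))
  h_star <- 3 * (length(fn) + 1) / nrow(Xtr)
  mu <- colMeans(xtr)
  sdv <- apply(xtr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  ztr <- sweep(sweep(xtr, 2, mu), 2, sdv, "/")
  abs_res <- abs(member$train_y -
                   predict(member$model, member$train_features))
  list(fn = fn, xtx_inv = xtx_inv, h_star = h_star,
       mu = mu, sd = sdv, ztr = ztr, abs_res = abs_res)
}

#' Intelligent consensus prediction over multiple linear models
#'
#' Combines the predictions of two or more fitted models for the same
#' records. A member model is *qualified* for a record when the record
#' lies inside that model's leverage applicability domain (`h <= h*`
#' computed from the member's own training design). Per-record weights
#' and best-model choices use the member's mean absolute training error
#' over the `k` nearest training records, measured by Euclidean distance
#' in the member's standardized (training mean/SD) feature space.
#' Records for which no member qualifies fall back to the CM0 average and
#' are flagged in the trace.
#'
#' @param members list of [consensus_member()] objects (>= 2).
#' @param newdata data frame containing every member's feature columns for
#'   the records to predict.
#' @param config a [consensus_config()].
#' @return List with `predictions` (numeric vector) and `trace` (data
#'   frame with per-record qualification counts, fallback flag, and for
#'   CM3 the chosen member index).
#' @export
consensus_predict <- function(members, newdata, config = consensus_config()) {
  if (length(members) < 2) stop("need at least 2 member models", call. = FALSE)
  newdata <- as.data.frame(newdata)
  n <- nrow(newdata)
  m <- length(members)
  ctx <- lapply(members, .member_context)
  preds <- vapply(members, function(mb) predict(mb$model, newdata), numeric(n))
  preds <- matrix(preds, nrow = n, ncol = m)
  qual <- matrix(FALSE, n, m)
  nbr_mae <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    cj <- ctx[[j]]
    xm <- as.matrix(newdata[, cj$fn, drop = FALSE])
    Xm <- cbind(1, xm)
    h <- rowSums((Xm %*% cj$xtx_inv) * Xm)
    qual[, j] <- h <= cj$h_star
    if (config$strategy %in% c("CM2", "CM3")) {
      z <- sweep(sweep(xm, 2, cj$mu), 2, cj$sd, "/")
      k <- min(config$k, nrow(cj$ztr))
      for (i in seq_len(n)) {
        d2 <- colSums((t(cj$ztr) - z[i, ])^2)
        nearest <- order(d2)[seq_len(k)]
        nbr_mae[i, j] <- mean(cj$abs_res[nearest])
      }
    }
  }
  out <- numeric(n)
  chosen <- rep(NA_integer_, n)
  fallback <- rep(FALSE, n)
  for (i in seq_len(n)) {
    q <- which(qual[i, ])
    if (config$strategy == "CM0" || length(q) == 0) {
      out[i] <- mean(preds[i, ])
      fallback[i] <- config$strategy != "CM0" && length(q) == 0
    } else if (config$strategy == "CM1") {
      out[i] <- mean(preds[i, q])
    } else if (config$strategy == "CM2") {
      w <- 1 / nbr_mae[i, q]
      if (!all(is.finite(w))) w <- rep(1, length(q))  # zero neighborhood error
      w <- w / sum(w)
      out[i] <- sum(w * preds[i, q])
    } else {  # CM3
      chosen[i] <- q[which.min(nbr_mae[i, q])]
      out[i] <- preds[i, chosen[i]]
    }
  }
  list(predictions = out,
       trace = data.frame(n_qualified = rowSums(qual),
                          fallback_cm0 = fallback,
                          chosen_model = chosen))
}
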