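literal_loo <- function(x, y) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    if (is.null(x)) {
      y[i] - mean(y[-i])
    } else {
      fit <- fit_ols(x[-i, , drop = FALSE], y[-i])
      y[i] - predict(fit, x[i, , drop = FALSE])
    }
  }, numeric(1))
}

test_that("LOO hand example: intercept-only on y = 1,2,3", {
  res <- q2_mae_loo(data.frame(dummy = 1:3), c(1, 2, 3), NULL)
  # deleted predictions are 2.5, 2.0, 1.5
  expect_equal(res$q2_loo, -1.25)
  expect_equal(res$mae_loo, 1.0)
  # exact linear data
  x <- data.frame(f = 1:10)
  res2 <- q2_mae_loo(x, 2 * (1:10) + 1, "f")
  expect_equal(res2$q2_loo, 1)
  expect_equal(res2$mae_loo, 0, tolerance = 1e-12)
})

test_that("hat-matrix LOO equals the literal refit loop", {
  for (seed in 1:10) {
    sys <- random_system(30, 2, seed)
    res <- q2_mae_loo(sys$x, sys$y, names(sys$x))
    e <- literal_loo(sys$x, sys$y)
    expect_equal(res$mae_loo, mean(abs(e)), tolerance = 1e-10)
    expect_equal(res$q2_loo,
                 1 - sum(e^2) / sum((sys$y - mean(sys$y))^2),
                 tolerance = 1e-10)
  }
})

test_that("leave-chemical-out pooling matches a literal per-chemical refit", {
  pairs <- data.frame(comp1 = c("a", "a", "b"), comp2 = c("x", "y", "y"),
                      n = c(4, 5, 4))
  ds <- make_pair_dataset(pairs)
  withr::with_seed(8, {
    feats <- data.frame(f1 = rnorm(nrow(ds)), f2 = rnorm(nrow(ds)))
    y <- 30 + 2 * feats$f1 - feats$f2 + rnorm(nrow(ds))
  })
  got <- q2_mae_lco(ds, feats, y, c("f1", "f2"))
  # independent loop
  obs <- c(); pred <- c()
  for (ch in unique(c(ds$comp1_id, ds$comp2_id))) {
    held <- ds$comp1_id == ch | ds$comp2_id == ch
    fit <- fit_ols(feats[!held, ], y[!held])
    obs <- c(obs, y[held])
    pred <- c(pred, predict(fit, feats[held, ]))
  }
  expect_equal(got$mae_lco, mean(abs(obs - pred)), tolerance = 1e-12)
  expect_equal(got$q2_lco, 1 - sum((obs - pred)^2) /
                 sum((obs - mean(obs))^2), tolerance = 1e-12)
})

test_that("LCO equals LOO when every chemical occurs in one record", {
  pairs <- data.frame(comp1 = c("a", "b", "c", "d"),
                      comp2 = c("w", "x", "y", "z"), n = 1)
  ds <- make_pair_dataset(pairs)
  y <- ds$sigma_mN_per_m
  feats <- data.frame(dummy = seq_len(nrow(ds)))
  loo <- q2_mae_loo(feats, y, NULL)
  lco <- q2_mae_lco(ds, feats, y, character(0))
  expect_equal(lco$q2_lco, loo$q2_loo)
  expect_equal(lco$mae_lco, loo$mae_loo)
})

test_that("external metrics follow their closed forms", {
  expect_equal(r2_pred(c(50, 60), c(52, 57), 54), 0.75)
  expect_equal(r2_pred(1:5, 1:5, 3), 1)
  expect_equal(r2_pred(c(1, 2), c(3, 3), 3), 0)  # predictions at train mean
  expect_error(r2_pred(c(3, 3), c(1, 2), 3), "denominator")

  expect_equal(aard(c(50), c(55))$aard, 10)
  expect_equal(aard(c(40, 50), c(44, 45))$aard, 10)
  expect_equal(aard(c(40, 50), c(40, 50))$aard, 0)
  expect_equal(aard(c(50), c(55))$rd, 10)
  expect_equal(aard(c(50), c(45))$rd, -10)
  expect_error(aard(c(0, 1), c(1, 1)), "zero")
  # order invariance
  withr::with_seed(2, { o <- runif(20, 30, 80); p <- o + rnorm(20) })
  perm <- sample(20)
  expect_equal(aard(o, p)$aard, aard(o[perm], p[perm])$aard)
  expect_equal(r2_pred(o, p, 50), r2_pred(o[perm], p[perm], 50))
})

test_that("rm2 metrics match an independently coded oracle", {
  oracle_rm2 <- function(obs, pred) {
    sc <- function(v) (v - min(v)) / (max(v) - min(v))
    u <- sc(obs); w <- sc(pred)
    r2 <- summary(lm(u ~ w))$r.squared
    k <- coef(lm(u ~ 0 + w))
    r02 <- 1 - sum((u - k * w)^2) / sum((u - mean(u))^2)
    kp <- coef(lm(w ~ 0 + u))
    r02p <- 1 - sum((w - kp * u)^2) / sum((w - mean(w))^2)
    c(rm2 = r2 * (1 - sqrt(max(0, r2 - r02))),
      rm2p = r2 * (1 - sqrt(max(0, r2 - r02p))))
  }
  withr::with_seed(17, {
    obs <- runif(10, 40, 80)
    pred <- obs + rnorm(10, sd = 4)
  })
  got <- rm2_metrics(obs, pred)
  want <- oracle_rm2(obs, pred)
  expect_equal(got$rm2, unname(want["rm2"]), tolerance = 1e-10)
  expect_equal(got$rm2_prime, unname(want["rm2p"]), tolerance = 1e-10)
  expect_equal(got$delta, abs(got$rm2 - got$rm2_prime))

  # identity and offset-only predictions are perfect after scaling
  ident <- rm2_metrics(obs, obs)
  expect_equal(ident$rm2, 1)
  expect_equal(ident$delta, 0)
  lin <- rm2_metrics(obs, 2 * obs + 7)
  expect_equal(lin$rm2, 1)
})

test_that("Y-randomization separates signal from noise", {
  withr::with_seed(55, {
    x <- as.data.frame(matrix(rnorm(200 * 3), 200, 3))
    names(x) <- paste0("f", 1:3)
    y_signal <- drop(5 + as.matrix(x) %*% c(4, -3, 2) + rnorm(200, sd = 0.3))
    y_noise <- rnorm(200)
  })
  rep_s <- y_randomization(x, y_signal, names(x), n_runs = 100, rng_seed = 1)
  expect_gt(rep_s$crp2, 0.8)
  expect_lte(rep_s$crp2, rep_s$r)
  rep_n <- y_randomization(x, y_noise, names(x), n_runs = 100, rng_seed = 1)
  expect_lt(rep_n$crp2, 0.25)
  # bit-reproducible given the seed
  rep_s2 <- y_randomization(x, y_signal, names(x), n_runs = 100, rng_seed = 1)
  expect_identical(rep_s$r2_random, rep_s2$r2_random)
  expect_error(y_randomization(x, y_noise, names(x), n_runs = 0), "n_runs")
})

test_that("leverages match the closed form and sum to p + 1", {
  withr::with_seed(23, x <- rnorm(25))
  x <- x - mean(x)  # centered predictor
  y <- 3 + 2 * x + withr::with_seed(24, rnorm(25))
  fit <- fit_ols(data.frame(f = x), y)
  ad <- williams(fit, data.frame(f = x), y)
  expect_equal(ad$leverage, 1 / 25 + x^2 / sum(x^2), tolerance = 1e-12)
  expect_equal(sum(ad$leverage), 2, tolerance = 1e-12)
  expect_equal(attr(ad, "h_star"), 3 * 2 / 25)
  # a record at the training centroid has h = 1/n
  ad2 <- williams(fit, data.frame(f = x), y,
                  probe = list(features = data.frame(f = 0), y = 3))
  expect_equal(ad2$leverage[ad2$set == "probe"], 1 / 25, tolerance = 1e-12)
  # flags follow the documented thresholds
  expect_equal(ad$structural_outlier, ad$leverage > attr(ad, "h_star"))
  expect_equal(ad$response_outlier, abs(ad$std_residual) > 3)
})

test_that("validation_report assembles a coherent battery", {
  syn <- generate_synthetic(synthetic_config(seed = 77))
  ds <- syn$dataset
  sp <- mo_split(ds, 2, 3)
  tr <- ds$record_id %in% sp$train_ids
  feats <- build_features(ds, syn$descriptors, 1)
  ftr <- filter_features(feats[tr, , drop = FALSE])
  y <- ds$sigma_mN_per_m
  model <- suppressWarnings(sfs_select(ftr, y[tr], "R2"))
  rep <- validation_report(model, split_subset(ds, sp, "train"), ftr, y[tr],
                           feats[!tr, names(ftr), drop = FALSE], y[!tr])
  expect_lte(rep$q2_loo, 1)
  expect_lte(rep$q2_lco, 1)
  expect_lte(rep$test$r2_pred, 1)
  expect_gte(rep$test$aard, 0)
  expect_gt(rep$q2_loo, 0.9)  # strong planted signal
})
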