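test_that("fit_ols reproduces exact and normal-equation solutions", {
  f1 <- seq(0, 9)
  y <- 2 * f1 + 1
  fit <- fit_ols(data.frame(f1 = f1), y)
  expect_equal(unname(fit$coefficients), 2)
  expect_equal(fit$intercept, 1)
  expect_equal(fit$r2, 1)

  # constant response: R2 reported as 0 by convention
  fitc <- fit_ols(data.frame(f1 = f1), rep(3, 10))
  expect_equal(fitc$r2, 0)

  # random 20x3 system vs explicit (X'X)^-1 X'y oracle
  sys <- random_system(20, 3, seed = 42)
  fit2 <- fit_ols(sys$x, sys$y)
  X <- cbind(1, as.matrix(sys$x))
  beta <- solve(t(X) %*% X) %*% t(X) %*% sys$y
  expect_equal(unname(c(fit2$intercept, fit2$coefficients)),
               unname(drop(beta)), tolerance = 1e-8)
  # standard errors against the closed form
  res <- sys$y - X %*% beta
  s2 <- sum(res^2) / (20 - 4)
  expect_equal(unname(fit2$se),
               unname(sqrt(diag(solve(t(X) %*% X)) * s2)), tolerance = 1e-8)
})

test_that("rank-deficient designs fail naming the dependent column", {
  x <- data.frame(f1 = 1:10, f2 = 2 * (1:10))
  expect_error(fit_ols(x, rnorm(10)), "f2")
})

test_that("residuals are orthogonal to the selected columns", {
  sys <- random_system(40, 4, seed = 7)
  fit <- fit_ols(sys$x, sys$y)
  for (col in names(sys$x)) {
    xv <- sys$x[[col]]
    expect_lt(abs(sum(xv * fit$residuals)),
              1e-6 * sqrt(sum(xv^2)) * sqrt(sum(fit$residuals^2)) + 1e-12)
  }
})

test_that("forward selection recovers a planted noise-free signal", {
  withr::with_seed(31, {
    x <- as.data.frame(matrix(rnorm(100 * 12), 100, 12))
    names(x) <- paste0("f", 1:12)
    y <- 3 * x$f1 - 2 * x$f2 + rnorm(100, sd = 1e-8)
  })
  model <- sfs_select(x, y, scoring = "R2")
  expect_setequal(model$feature_names, c("f1", "f2"))
  expect_equal(unname(model$coefficients[order(names(model$coefficients))]),
               c(3, -2), tolerance = 1e-4)
  # single strongly predictive candidate
  m1 <- sfs_select(x["f1"], 5 * x$f1 + rnorm(100, sd = 1e-8), scoring = "R2")
  expect_equal(m1$feature_names, "f1")
})

test_that("the error-reduction policy gates every accepted step", {
  syn <- generate_synthetic(synthetic_config(seed = 13))
  ff <- filter_features(build_features(syn$dataset, syn$descriptors, 1))
  model <- sfs_select(ff, syn$dataset$sigma_mN_per_m, "R2", mae_reduction = 0.05)
  trace <- attr(model, "trace")
  acc <- trace[trace$accepted, ]
  expect_true(all(acc$mae_loo_after <= 0.95 * acc$mae_loo_before))
  # selection stops at the first rejection: at most one rejected row, last
  expect_lte(sum(!trace$accepted), 1)
  if (any(!trace$accepted)) {
    expect_false(trace$accepted[nrow(trace)])
  }
})

test_that("a useless candidate pool yields an intercept-only model", {
  withr::with_seed(100, {
    x <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
    y <- rnorm(60)  # pure noise response
  })
  expect_warning(model <- sfs_select(x, y, scoring = "R2"), "intercept-only")
  expect_length(model$feature_names, 0)
  expect_equal(model$intercept, mean(y))
  expect_true(isTRUE(attr(model, "intercept_only")))
})

test_that("cross-validated scorings are deterministic given the seed", {
  syn <- generate_synthetic(synthetic_config(n_mixtures = 30, seed = 21))
  ff <- filter_features(build_features(syn$dataset, syn$descriptors, 1))
  y <- syn$dataset$sigma_mN_per_m
  m1 <- suppressWarnings(sfs_select(ff, y, "R2_cv5", cv_seed = 5))
  m2 <- suppressWarnings(sfs_select(ff, y, "R2_cv5", cv_seed = 5))
  expect_identical(m1$feature_names, m2$feature_names)
  expect_identical(m1$coefficients, m2$coefficients)
})

test_that("predict applies intercept plus coefficients row-wise", {
  fit <- fit_ols(data.frame(f1 = c(0, 1, 2, 5, 7, 9)),
                 1 + 2 * c(0, 1, 2, 5, 7, 9))
  expect_equal(predict(fit, data.frame(f1 = c(0, 1, 2))), c(1, 3, 5))
  expect_error(predict(fit, data.frame(g = 1:3)), "f1")
})

test_that("model JSON serialization round-trips predictions", {
  sys <- random_system(30, 3, seed = 3)
  fit <- fit_ols(sys$x, sys$y)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(fit, path)
  back <- read_model(path)
  expect_equal(back$feature_names, fit$feature_names)
  expect_equal(predict(back, sys$x), predict(fit, sys$x), tolerance = 1e-12)
  expect_equal(back$r2, fit$r2, tolerance = 1e-12)
})
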