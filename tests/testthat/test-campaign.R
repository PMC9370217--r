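toy_campaign <- function(seed = 101) {
  syn <- generate_synthetic(synthetic_config(n_mixtures = 30, seed = seed))
  cfg <- campaign_config(schemes = "MO", methods = c(1, 2),
                         scorings = c("R2", "NMAE"),
                         max_seed = 3, max_interval = 3,
                         external = NULL)
  list(syn = syn, cfg = cfg)
}

test_that("a campaign attempts every split x method x scoring cell", {
  tc <- toy_campaign()
  splits <- enumerate_valid_splits(tc$syn$dataset, "MO", 3, 3)
  expect_gt(length(splits), 0)
  res <- run_campaign(tc$syn$dataset, tc$syn$descriptors, tc$cfg)
  expect_equal(length(res$cells) + length(res$failures),
               length(splits) * 2 * 2)
})

test_that("campaigns are deterministic and recover the planted model", {
  tc <- toy_campaign(seed = 202)
  res1 <- run_campaign(tc$syn$dataset, tc$syn$descriptors, tc$cfg)
  res2 <- run_campaign(tc$syn$dataset, tc$syn$descriptors, tc$cfg)
  r1 <- rank_models(res1); r2 <- rank_models(res2)
  expect_identical(r1, r2)
  top <- res1$cells[[r1$cell_id[1]]]
  expect_true(all(tc$syn$truth$feature_names %in% top$model$feature_names))
})

test_that("external carve-out happens once, before split enumeration", {
  syn <- generate_synthetic(synthetic_config(n_mixtures = 40, seed = 303))
  cfg <- campaign_config(schemes = "MO", methods = 1, scorings = "R2",
                         max_seed = 3, max_interval = 3,
                         external = list(scheme = "CO", seed = 3, interval = 4))
  res <- run_campaign(syn$dataset, syn$descriptors, cfg)
  expect_false(is.null(res$external_split))
  ext_ids <- res$external_split$test_ids
  for (cell in res$cells) {
    expect_length(intersect(cell$split$train_ids, ext_ids), 0)
    expect_length(intersect(cell$split$test_ids, ext_ids), 0)
    expect_false(is.null(cell$report$external))
  }
})

test_that("ranking averages the three predictivity statistics", {
  df <- data.frame(
    cell_id = c("a", "b", "c"),
    q2_loo = c(0.908, 0.884, 0.90), q2_lco = c(0.882, 0.854, 0.90),
    r2_pred_test = c(0.783, 0.907, 0.90), mae_test = c(5.134, 3.863, 1.0))
  ranked <- rank_models(df)
  expect_equal(ranked$avg[ranked$cell_id == "a"], mean(c(0.908, 0.882, 0.783)))
  expect_equal(ranked$avg[ranked$cell_id == "b"], mean(c(0.884, 0.854, 0.907)))
  expect_equal(ranked$cell_id[1], "c")  # 0.90 beats both
  # all-equal scores fall back to MAE_test ascending
  df2 <- data.frame(cell_id = c("x", "y"), q2_loo = 0.9, q2_lco = 0.9,
                    r2_pred_test = 0.9, mae_test = c(2, 1))
  expect_equal(rank_models(df2)$cell_id, c("y", "x"))
  # missing statistic excludes the cell with a warning
  df3 <- df; df3$q2_lco[2] <- NA
  expect_warning(r3 <- rank_models(df3), "excluded")
  expect_false("b" %in% r3$cell_id)
})

test_that("final_score averages four statistics", {
  # published component statistics are printed to 3 decimals, so the
  # recomputed averages can sit half a unit in the last place away
  expect_lt(abs(final_score(0.908, 0.882, 0.783, 0.862) - 0.859), 6e-4)
  expect_lt(abs(final_score(0.906, 0.854, 0.830, 0.688) - 0.820), 6e-4)
  expect_equal(final_score(0.7, 0.7, 0.7, 0.7), 0.7)
})

test_that("top-model retention deduplicates identical solutions", {
  tc <- toy_campaign(seed = 404)
  res <- run_campaign(tc$syn$dataset, tc$syn$descriptors, tc$cfg)
  ranked <- rank_models(res)
  top <- top_unique_models(res, ranked, n = 5)
  expect_lte(nrow(top), 5)
  sigs <- vapply(top$cell_id, function(id) {
    cell <- res$cells[[id]]
    paste(paste(sort(cell$split$test_ids), collapse = ","),
          paste(sort(cell$model$feature_names), collapse = ","), sep = "||")
  }, character(1))
  expect_false(anyDuplicated(sigs) > 0)
})

test_that("campaign config round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("schemes: [MO]", "methods: [1]", "scorings: [R2, NMAE]",
               "max_seed: 3", "max_interval: 2", "top_n: 5"), path)
  cfg <- read_campaign_config(path)
  expect_equal(cfg$schemes, "MO")
  expect_equal(cfg$max_seed, 3)
  expect_equal(cfg$scorings, c("R2", "NMAE"))
  expect_equal(cfg$top_n, 5)
})
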