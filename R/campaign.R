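#' Campaign configuration
#'
#' Settings for a full model-building campaign over data splits,
#' descriptor calculation methods and forward-selection scoring
#' conditions. An external validation set can be carved out first with a
#' compounds-out split (applied once, before split enumeration).
#'
#' @param schemes splitting schemes to enumerate (`"MO"`, `"CO"`).
#' @param methods descriptor methods (1 = pmix only, 2 = pmix + nmix).
#' @param scorings forward-selection scoring criteria (see [sfs_select()]).
#' @param max_seed,max_interval split enumeration bounds.
#' @param min_test_frac minimum test/train size ratio.
#' @param external `NULL`, or `list(scheme, seed, interval)` describing the
#'   one-off carve-out of the external validation set.
#' @param mae_reduction forward-selection acceptance policy threshold.
#' @param variance_cutoff,correlation_cutoff feature-filter cutoffs.
#' @param top_n number of unique top models to retain.
#' @param cv_seed global seed for cross-validated scorings.
#' @return A `campaign_config` list.
#' @export
campaign_config <- function(schemes = c("MO", "CO"), methods = c(1, 2),
                            scorings = c("R2", "NMAE"),
                            max_seed = 6, max_interval = 6,
                            min_test_frac = 0.15,
                            external = list(scheme = "CO", seed = 3, interval = 4),
                            mae_reduction = 0.05,
                            variance_cutoff = 0.001, correlation_cutoff = 0.95,
                            top_n = 15, cv_seed = 1) {
  structure(list(schemes = schemes, methods = methods, scorings = scorings,
                 max_seed = max_seed, max_interval = max_interval,
                 min_test_frac = min_test_frac, external = external,
                 mae_reduction = mae_reduction,
                 variance_cutoff = variance_cutoff,
                 correlation_cutoff = correlation_cutoff,
                 top_n = top_n, cv_seed = cv_seed),
            class = "campaign_config")
}

#' Read a campaign configuration from YAML
#' @param path YAML file path with fields matching [campaign_config()].
#' @return A `campaign_config`.
#' @export
read_campaign_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(campaign_config, vals[intersect(names(vals),
                                          names(formals(campaign_config)))])
}

#' Run a model-building campaign
#'
#' Orchestrates the full workflow: optionally carves out an external
#' validation set with a one-off compounds-out split, enumerates every
#' admissible (seed, interval) split under each scheme, and for every
#' split x descriptor method x scoring condition builds the weighted
#' mixture features, filters them on the training rows only (the
#' surviving column list is then applied to all sets), runs
#' forward-selection MLR and assembles the validation report. Individual
#' cell failures are recorded and the campaign continues. The result is a
#' pure function of (dataset, descriptor table, config).
#'
#' @param dataset a [mixture_dataset()] with responses.
#' @param descriptor_table a [descriptor_table()].
#' @param config a [campaign_config()].
#' @return A `campaign_result`: list with `cells` (per-cell list of
#'   `model`, `split`, `report`, `method`, `scoring`), `failures`, and
#'   `external_split` (or `NULL`).
#' @export
run_campaign <- function(dataset, descriptor_table, config = campaign_config()) {
  ext_split <- NULL
  modeling <- dataset
  ext_ds <- NULL
  if (!is.null(config$external)) {
    splitter <- if (config$external$scheme == "MO") mo_split else co_split
    ext_split <- splitter(dataset, config$external$seed, config$external$interval)
    modeling <- split_subset(dataset, ext_split, "train")
    ext_ds <- split_subset(dataset, ext_split, "test")
  }
  cells <- list(); failures <- list()
  for (scheme in config$schemes) {
    splits <- enumerate_valid_splits(modeling, scheme, config$max_seed,
                                     config$max_interval, config$min_test_frac)
    for (sp in splits) {
      for (method in config$methods) {
        feats_all <- build_features(modeling, descriptor_table, method)
        feats_ext <- if (!is.null(ext_ds)) {
          build_features(ext_ds, descriptor_table, method)
        } else NULL
        tr <- modeling$record_id %in% sp$train_ids
        feats_tr <- filter_features(feats_all[tr, , drop = FALSE],
                                    config$variance_cutoff,
                                    config$correlation_cutoff)
        kept <- names(feats_tr)
        for (scoring in config$scorings) {
          cell_id <- sprintf("%s_s%d_i%d_m%d_%s", scheme, sp$spec$seed,
                             sp$spec$interval, method, scoring)
          res <- tryCatch({
            y_tr <- modeling$sigma_mN_per_m[tr]
            model <- suppressWarnings(
              sfs_select(feats_tr, y_tr, scoring,
                         config$mae_reduction, config$cv_seed))
            report <- validation_report(
              model,
              split_subset(modeling, sp, "train"),
              feats_tr, y_tr,
              feats_all[!tr, kept, drop = FALSE],
              modeling$sigma_mN_per_m[!tr],
              if (!is.null(feats_ext)) feats_ext[, kept, drop = FALSE] else NULL,
              if (!is.null(ext_ds)) ext_ds$sigma_mN_per_m else NULL)
            list(cell_id = cell_id, model = model, split = sp,
                 method = method, scoring = scoring, report = report)
          }, error = function(e) e)
          if (inherits(res, "error")) {
            failures[[cell_id]] <- conditionMessage(res)
          } else {
            cells[[cell_id]] <- res
          }
        }
      }
    }
  }
  structure(list(cells = cells, failures = failures,
                 external_split = ext_split),
            class = "campaign_result")
}

#' Rank campaign models by averaged predictivity
#'
#' Each model's score is the arithmetic mean of `Q2_LOO`, `Q2_LCO` and
#' `R2_Pred` on the test set; models are ordered by score descending with
#' ties broken by test-set MAE ascending. Cells missing any of the three
#' statistics are excluded with a warning.
#'
#' @param results a `campaign_result`, or a data frame with columns
#'   `q2_loo`, `q2_lco`, `r2_pred_test`, `mae_test` (and optionally
#'   `model`).
#' @return Data frame of ranked cells with an `avg` column.
#' @export
rank_models <- function(results) {
  if (inherits(results, "campaign_result")) {
    rows <- lapply(results$cells, function(cell) {
      data.frame(cell_id = cell$cell_id,
                 scheme = cell$split$spec$scheme,
                 seed = cell$split$spec$seed,
                 interval = cell$split$spec$interval,
                 method = cell$method, scoring = cell$scoring,
                 n_tr = cell$model$n_tr,
                 n_features = length(cell$model$feature_names),
                 q2_loo = cell$report$q2_loo,
                 q2_lco = cell$report$q2_lco,
                 r2_pred_test = cell$report$test$r2_pred,
                 mae_test = cell$report$test$mae,
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
  } else {
    df <- as.data.frame(results)
  }
  needed <- c("q2_loo", "q2_lco", "r2_pred_test")
  ok <- stats::complete.cases(df[, needed])
  if (any(!ok)) {
    warning(sum(!ok), " cell(s) excluded: missing ranking statistic")
    df <- df[ok, , drop = FALSE]
  }
  df$avg <- rowMeans(df[, needed])
  df <- df[order(-df$avg, df$mae_test), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Final model score over four predictivity statistics
#'
#' Arithmetic mean of `Q2_LOO`, `Q2_LCO` and the two external
#' determination coefficients (`R2_Pred` on the test set and on the
#' external validation set), used to pick the overall best model among
#' finalists.
#'
#' @param q2_loo,q2_lco,r2_pred_test,r2_pred_ext the four statistics.
#' @return Their arithmetic mean.
#' @export
final_score <- function(q2_loo, q2_lco, r2_pred_test, r2_pred_ext) {
  (q2_loo + q2_lco + r2_pred_test + r2_pred_ext) / 4
}

#' Retain the top unique models of a ranked campaign
#'
#' Walks the ranked list keeping the first occurrence of each unique
#' (split partition, feature set) pair until `n` models are retained.
#'
#' @param results a `campaign_result`.
#' @param ranked output of [rank_models()] on the same result.
#' @param n number of unique models to keep (default 15).
#' @return Subset of `ranked` (<= n rows).
#' @export
top_unique_models <- function(results, ranked, n = 15) {
  seen <- character(0)
  keep <- logical(nrow(ranked))
  for (i in seq_len(nrow(ranked))) {
    cell <- results$cells[[ranked$cell_id[i]]]
    sig <- paste(paste(sort(cell$split$test_ids), collapse = ","),
                 paste(sort(cell$model$feature_names), collapse = ","),
                 sep = "||")
    if (!(sig %in% seen)) {
      seen <- c(seen, sig)
      keep[i] <- TRUE
    }
    if (sum(keep) >= n) break
  }
  ranked[keep, , drop = FALSE]
}
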