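#' Configuration for the synthetic mixture-data generator
#'
#' Defaults emulate the structure of a binary deep-eutectic-solvent
#' surface-tension study: a library of salt-cation HBAs and molecular
#' HBDs, mixtures at small-integer molar ratios, measurements over the
#' 278.15-358.15 K temperature grid in 20 K steps, responses near
#' 40-90 mN/m generated from a known linear model in weighted-mixture
#' descriptor space with 1 mN/m Gaussian noise, and injected constant and
#' collinear nuisance descriptors that the feature filter must remove.
#' With the default 60 mixtures x 5 temperatures the dataset has 300
#' records.
#'
#' @param n_hba,n_hbd number of components per role.
#' @param n_mixtures number of unique mixtures (HBA, HBD, ratio triples).
#' @param ratios list of integer molar ratios `c(a, b)` to sample from.
#' @param temperatures temperature grid in kelvin.
#' @param n_descriptors total per-component descriptors.
#' @param n_informative how many descriptors carry true signal (through
#'   their `_pmix` columns).
#' @param coefficients true coefficients of the informative `_pmix`
#'   columns (length `n_informative`).
#' @param beta_T true temperature coefficient (mN/m per K).
#' @param intercept true intercept (mN/m).
#' @param noise_sd Gaussian noise SD (mN/m).
#' @param n_constant,n_collinear number of nuisance descriptors that are
#'   constant across components / exact duplicates of other descriptors.
#' @param seed RNG seed; the full output is bit-reproducible given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_hba = 15, n_hbd = 25, n_mixtures = 60,
                             ratios = list(c(1, 1), c(1, 2), c(1, 3),
                                           c(1, 4), c(2, 1)),
                             temperatures = seq(278.15, 358.15, by = 20),
                             n_descriptors = 30, n_informative = 5,
                             coefficients = c(4, -3, 3.5, -2.5, 2),
                             beta_T = -0.104, intercept = 90,
                             noise_sd = 1, n_constant = 3, n_collinear = 3,
                             seed = 1) {
  if (n_informative > n_descriptors) {
    stop("n_informative must not exceed n_descriptors", call. = FALSE)
  }
  if (length(coefficients) != n_informative) {
    stop("coefficients must have length n_informative", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (n_informative + n_constant + n_collinear > n_descriptors) {
    stop("informative + nuisance descriptors exceed n_descriptors",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "synthetic_config")
}

#' Generate a synthetic mixture dataset with known ground truth
#'
#' Draws per-component descriptor vectors from standard normal
#' distributions, samples unique (HBA, HBD, ratio) mixtures, and for each
#' mixture x temperature generates the response
#' `sigma = intercept + sum(beta_j * pmix_j) + beta_T * T + N(0, noise_sd)`
#' where the informative `pmix` columns follow the weighted-mixture
#' formula exactly as [build_features()] computes them. Nuisance
#' descriptors are injected per the config: `n_constant` descriptors take
#' the same value for every component (their `pmix` columns are constant)
#' and `n_collinear` descriptors are exact copies of other descriptors
#' (their `pmix` columns are perfectly correlated). Halide flags are
#' assigned per HBA (chloride with probability 0.7, else bromide) and do
#' not enter the true model.
#'
#' @param config a [synthetic_config()].
#' @return List with `dataset` (a [mixture_dataset()]), `descriptors`
#'   (a [descriptor_table()]), and `truth` (a `linear_model` holding the
#'   generating intercept/coefficients on the WM feature columns,
#'   including `temperature`).
#' @export
generate_synthetic <- function(config = synthetic_config()) {
  withr::with_seed(config$seed, .generate_synthetic(config))
}

.generate_synthetic <- function(cfg) {
  hba_ids <- sprintf("HBA%02d", seq_len(cfg$n_hba))
  hbd_ids <- sprintf("HBD%02d", seq_len(cfg$n_hbd))
  comp_ids <- c(hba_ids, hbd_ids)
  dnames <- sprintf("D%02d", seq_len(cfg$n_descriptors))
  desc <- matrix(stats::rnorm(length(comp_ids) * cfg$n_descriptors),
                 nrow = length(comp_ids),
                 dimnames = list(comp_ids, dnames))
  ninf <- cfg$n_informative
  const_idx <- if (cfg$n_constant > 0) ninf + seq_len(cfg$n_constant) else integer(0)
  coll_idx <- if (cfg$n_collinear > 0) {
    ninf + cfg$n_constant + seq_len(cfg$n_collinear)
  } else integer(0)
  for (j in const_idx) desc[, j] <- stats::rnorm(1)
  for (i in seq_along(coll_idx)) {
    # duplicate informative descriptors cyclically
    desc[, coll_idx[i]] <- desc[, ((i - 1) %% ninf) + 1]
  }
  # unique mixture triples
  grid <- expand.grid(hba = hba_ids, hbd = hbd_ids,
                      ratio = seq_along(cfg$ratios),
                      stringsAsFactors = FALSE)
  pick <- sample(nrow(grid), cfg$n_mixtures)
  mixtures <- grid[pick, , drop = FALSE]
  cl <- stats::setNames(stats::rbinom(cfg$n_hba, 1, 0.7), hba_ids)
  rows <- list()
  rid <- 0L
  for (i in seq_len(nrow(mixtures))) {
    r <- cfg$ratios[[mixtures$ratio[i]]]
    x1 <- r[1] / sum(r)
    for (tk in cfg$temperatures) {
      rid <- rid + 1L
      rows[[rid]] <- data.frame(
        record_id = sprintf("R%04d", rid),
        comp1_id = mixtures$hba[i],
        comp1_smiles = paste0("C.", mixtures$hba[i]),  # synthetic placeholder
        comp2_id = mixtures$hbd[i],
        comp2_smiles = paste0("O.", mixtures$hbd[i]),
        x1 = x1, x2 = 1 - x1, temperature_K = tk,
        cl_flag = cl[[mixtures$hba[i]]],
        br_flag = 1 - cl[[mixtures$hba[i]]],
        sigma_mN_per_m = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  table <- descriptor_table(cbind(component_id = comp_ids,
                                  as.data.frame(desc)))
  inf_cols <- paste0(dnames[seq_len(ninf)], "_pmix")
  d1 <- desc[df$comp1_id, seq_len(ninf), drop = FALSE]
  d2 <- desc[df$comp2_id, seq_len(ninf), drop = FALSE]
  pm <- df$x1 * d1 + df$x2 * d2
  signal <- cfg$intercept + drop(pm %*% cfg$coefficients) +
    cfg$beta_T * df$temperature_K
  df$sigma_mN_per_m <- signal + stats::rnorm(nrow(df), sd = cfg$noise_sd)
  truth_coefs <- stats::setNames(c(cfg$coefficients, cfg$beta_T),
                                 c(inf_cols, "temperature"))
  truth <- structure(list(
    feature_names = names(truth_coefs),
    intercept = cfg$intercept, coefficients = truth_coefs,
    se = NULL, r2 = NA_real_, r2_adj = NA_real_, f_stat = NA_real_,
    n_tr = nrow(df), rho = NA_real_, sigma = cfg$noise_sd,
    df_residual = NA_integer_, fitted = NULL, residuals = NULL,
    hat = NULL, xtx_inv = NULL
  ), class = "linear_model")
  list(dataset = mixture_dataset(df, provenance = "synthetic"),
       descriptors = table, truth = truth)
}
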