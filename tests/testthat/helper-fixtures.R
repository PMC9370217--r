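# Shared fixtures built in code: tiny hand-checkable datasets.

# A minimal well-formed dataset data frame; occurrence profile controlled
# by `counts` (named vector: mixture label -> number of temperature
# points). Components are derived from the label so distinct labels give
# distinct mixtures.
make_dataset_df <- function(counts, x1 = 0.5) {
  rows <- list()
  rid <- 0
  for (lab in names(counts)) {
    for (j in seq_len(counts[[lab]])) {
      rid <- rid + 1
      rows[[rid]] <- data.frame(
        record_id = sprintf("r%03d", rid),
        comp1_id = paste0("A_", lab), comp1_smiles = "CCO",
        comp2_id = paste0("B_", lab), comp2_smiles = "OCC",
        x1 = x1, x2 = 1 - x1,
        temperature_K = 278.15 + 10 * (j - 1),
        cl_flag = 1, br_flag = 0,
        sigma_mN_per_m = 50 + rid,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

make_dataset <- function(counts, x1 = 0.5) {
  mixture_dataset(make_dataset_df(counts, x1), provenance = "fixture")
}

# Dataset with explicit component pairs (for compounds-out scenarios).
# `pairs` is a data frame with comp1, comp2, n (records per pair).
make_pair_dataset <- function(pairs) {
  rows <- list()
  rid <- 0
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(pairs$n[i])) {
      rid <- rid + 1
      rows[[rid]] <- data.frame(
        record_id = sprintf("r%03d", rid),
        comp1_id = pairs$comp1[i], comp1_smiles = "CC",
        comp2_id = pairs$comp2[i], comp2_smiles = "OO",
        x1 = 1 / 3, x2 = 2 / 3,
        temperature_K = 298.15 + 5 * (j - 1),
        cl_flag = 0, br_flag = 1,
        sigma_mN_per_m = 40 + rid,
        stringsAsFactors = FALSE)
    }
  }
  mixture_dataset(do.call(rbind, rows), provenance = "fixture")
}

# Random regression system for oracle checks.
random_system <- function(n, p, seed) {
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(x) <- paste0("f", seq_len(p))
    beta <- rnorm(p)
    y <- drop(1 + as.matrix(x) %*% beta + rnorm(n))
    list(x = x, y = y)
  })
}
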