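#' mixqspr: QSPR modeling of binary mixture properties
#'
#' Tools for building and validating quantitative structure-property
#' relationship (QSPR) models of binary mixtures such as deep eutectic
#' solvents (DES). The workflow covers molar-fraction-weighted mixture
#' descriptors, deterministic mixtures-out/compounds-out splitting,
#' forward-selection linear modeling under a leave-one-out error-reduction
#' policy, a full validation battery, consensus prediction, non-linear
#' baselines and a synthetic-data generator with known ground truth.
#'
#' @keywords internal
"_PACKAGE"

## Canonical column schema for mixture dataset CSV files. One row per
## measurement: component identities/SMILES, molar fractions, temperature,
## halide indicator flags for the salt anion, and the measured response
## (surface tension in mN/m; may be NA for prediction-only rows).
DATASET_COLUMNS <- c(
  "record_id", "comp1_id", "comp1_smiles", "comp2_id", "comp2_smiles",
  "x1", "x2", "temperature_K", "cl_flag", "br_flag", "sigma_mN_per_m"
)

AUX_COLUMNS <- c("temperature", "cl_flag", "br_flag")

#' Construct a validated binary-mixture dataset
#'
#' A `mixture_dataset` is a data frame with one row per measurement of a
#' binary mixture: component-1 is the hydrogen-bond acceptor (for salts, the
#' cation carries the identity; the halide anion is encoded by the
#' `cl_flag`/`br_flag` indicators), component-2 the hydrogen-bond donor.
#'
#' @param df data frame with the columns listed under [load_dataset()].
#' @param provenance character label recording where the data came from.
#' @return A `mixture_dataset` (a validated data frame).
#' @export
mixture_dataset <- function(df, provenance = "unknown") {
  missing_cols <- setdiff(DATASET_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("dataset schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- as.data.frame(df)[, DATASET_COLUMNS]
  df$record_id <- as.character(df$record_id)
  for (col in c("comp1_id", "comp1_smiles", "comp2_id", "comp2_smiles")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in c("x1", "x2", "temperature_K", "cl_flag", "br_flag",
                "sigma_mN_per_m")) {
    val <- df[[col]]
    if (!is.numeric(val)) {
      suppressWarnings(num <- as.numeric(val))
      bad <- which(!is.na(val) & is.na(num))
      if (length(bad) > 0) {
        stop(sprintf("dataset schema error: non-numeric value in '%s' at row %d",
                     col, bad[1]), call. = FALSE)
      }
      df[[col]] <- num
    }
  }
  .check_records(df)
  if (anyDuplicated(df$record_id)) {
    dup <- df$record_id[duplicated(df$record_id)][1]
    stop("dataset schema error: duplicated record_id '", dup, "'",
         call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance,
            class = c("mixture_dataset", "data.frame"))
}

.check_records <- function(df) {
  .fail <- function(row, field, why) {
    stop(sprintf("invalid record at row %d, field '%s': %s", row, field, why),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    x1 <- df$x1[i]; x2 <- df$x2[i]
    if (is.na(x1) || x1 <= 0 || x1 >= 1) .fail(i, "x1", "must lie in (0, 1)")
    if (is.na(x2) || x2 <= 0 || x2 >= 1) .fail(i, "x2", "must lie in (0, 1)")
    if (abs(x1 + x2 - 1) > 1e-9) {
      .fail(i, "x2", sprintf("molar fractions must sum to 1 (got %.10g)", x1 + x2))
    }
    tk <- df$temperature_K[i]
    if (is.na(tk) || tk <= 0) .fail(i, "temperature_K", "must be positive")
    for (fl in c("cl_flag", "br_flag")) {
      v <- df[[fl]][i]
      if (is.na(v) || !(v %in% c(0, 1))) .fail(i, fl, "must be 0 or 1")
    }
    s <- df$sigma_mN_per_m[i]
    if (!is.na(s) && s <= 0) .fail(i, "sigma_mN_per_m", "must be positive when present")
  }
  invisible(TRUE)
}

#' Read a binary-mixture dataset from CSV
#'
#' Expected columns (comma-separated, UTF-8, `.` decimal, header mandatory):
#' `record_id, comp1_id, comp1_smiles, comp2_id, comp2_smiles, x1, x2,
#' temperature_K, cl_flag, br_flag, sigma_mN_per_m`. SMILES strings are
#' stored verbatim; no structure standardization is performed. Row order is
#' preserved.
#'
#' @param path CSV file path.
#' @return A [mixture_dataset()].
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  mixture_dataset(df, provenance = path)
}

#' Write a mixture dataset to CSV
#'
#' Inverse of [load_dataset()]: a round trip preserves every field.
#'
#' @param dataset a [mixture_dataset()].
#' @param path output CSV path.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, DATASET_COLUMNS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.mixture_dataset <- function(x, ...) {
  cat(sprintf("mixture_dataset: %d records, %d unique mixtures (provenance: %s)\n",
              nrow(x), length(unique(mixture_key(x))), attr(x, "provenance")))
  print(utils::head(as.data.frame(x)), ...)
  if (nrow(x) > 6) cat(sprintf("... %d more rows\n", nrow(x) - 6L))
  invisible(x)
}

## Rational approximation of a fraction in (0,1) by continued-fraction
## convergents: smallest denominator q with |x - p/q| <= tol.
.rationalize <- function(x, tol = 1e-6, max_den = 10000L) {
  # continued fraction expansion of x; convergents p/q
  p0 <- 0L; q0 <- 1L; p1 <- 1L; q1 <- 0L
  r <- x
  repeat {
    a <- floor(r)
    p2 <- a * p1 + p0
    q2 <- a * q1 + q0
    if (q2 > max_den) return(NULL)
    if (q2 > 0 && abs(x - p2 / q2) <= tol) {
      return(c(p = as.integer(p2), q = as.integer(q2)))
    }
    frac <- r - a
    if (frac < .Machine$double.eps) return(NULL)
    r <- 1 / frac
    p0 <- p1; q0 <- q1; p1 <- p2; q1 <- q2
  }
}

#' Canonical mixture identity key
#'
#' A mixture is identified by its component pair plus its molar ratio;
#' records of the same DES measured at different temperatures share a key.
#' The molar ratio is reduced to lowest integer terms when the fractions are
#' rational within tolerance `1e-6` (e.g. `x1 = 0.333333` gives ratio
#' `1:2`); otherwise `x1` rounded to 4 decimals is used.
#'
#' @param dataset a [mixture_dataset()] (or any data frame with `comp1_id`,
#'   `comp2_id`, `x1`).
#' @return Character vector of keys, one per record.
#' @export
mixture_key <- function(dataset) {
  vapply(seq_len(nrow(dataset)), function(i) {
    x1 <- dataset$x1[i]
    pq <- .rationalize(x1)
    ratio <- if (is.null(pq)) {
      sprintf("x1=%.4f", round(x1, 4))
    } else {
      p <- pq[["p"]]; q <- pq[["q"]]
      a <- p; b <- q - p
      g <- .gcd(a, b)
      sprintf("%d:%d", a %/% g, b %/% g)
    }
    paste(dataset$comp1_id[i], dataset$comp2_id[i], ratio, sep = "|")
  }, character(1))
}

.gcd <- function(a, b) {
  while (b != 0) { t <- b; b <- a %% b; a <- t }
  a
}

#' Occurrence counts of mixtures or component chemicals
#'
#' Counts how often each unique mixture (or each unique chemical in a given
#' component role) occurs in the dataset, sorted by count descending with
#' ties broken by ascending lexicographic key. This ordering drives the
#' deterministic data-splitting schemes.
#'
#' @param dataset a [mixture_dataset()].
#' @param by one of `"mixture"`, `"component1"`, `"component2"`.
#' @return Data frame with columns `key`, `count`, sorted as described.
#' @export
occurrence_counts <- function(dataset, by = c("mixture", "component1", "component2")) {
  by <- match.arg(by)
  if (nrow(dataset) == 0) {
    return(data.frame(key = character(0), count = integer(0)))
  }
  keys <- switch(by,
    mixture    = mixture_key(dataset),
    component1 = dataset$comp1_id,
    component2 = dataset$comp2_id
  )
  tab <- table(keys)
  out <- data.frame(key = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  # C-locale ordering for platform-independent lexicographic tie-break
  lex <- withr::with_collate("C", order(out$key))
  out <- out[lex, , drop = FALSE]
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}
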