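#' Molar-fraction-weighted mixture descriptors
#'
#' For a binary mixture with component descriptor values `d1`, `d2` and
#' molar fractions `x1`, `x2` (summing to one), the two weighted-mixture
#' (WM) descriptor forms are
#' \deqn{D_{pmix} = x_1 D_1 + x_2 D_2}
#' \deqn{D_{nmix} = |x_1 D_1 - x_2 D_2|}
#' `pmix` is the molar-fraction-weighted mean; `nmix` captures the
#' asymmetry between the weighted contributions and is invariant to
#' swapping the two components.
#'
#' @param d1,d2 descriptor values of component 1 and 2.
#' @param x1,x2 molar fractions; must satisfy `x1 + x2 == 1` within `1e-9`.
#' @return Numeric vector of mixture descriptor values.
#' @export
pmix <- function(d1, d2, x1, x2) {
  .check_fractions(x1, x2)
  x1 * d1 + x2 * d2
}

#' @rdname pmix
#' @export
nmix <- function(d1, d2, x1, x2) {
  .check_fractions(x1, x2)
  abs(x1 * d1 - x2 * d2)
}

.check_fractions <- function(x1, x2) {
  if (any(abs(x1 + x2 - 1) > 1e-9)) {
    stop("molar fractions must sum to 1", call. = FALSE)
  }
  invisible(TRUE)
}

#' Load a per-component descriptor table
#'
#' CSV with first column `component_id` and one column per descriptor
#' (names taken verbatim, e.g. Dragon-style `MATS5s`, `BLTF96`). Every
#' component referenced by a dataset must be present and all values finite.
#'
#' @param path CSV file path.
#' @return Data frame with rownames set to component ids.
#' @export
load_descriptor_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "component_id") {
    stop("descriptor table must have 'component_id' as its first column",
         call. = FALSE)
  }
  descriptor_table(df)
}

#' @rdname load_descriptor_table
#' @param df data frame with a `component_id` first column.
#' @export
descriptor_table <- function(df) {
  df <- as.data.frame(df)
  ids <- as.character(df$component_id)
  if (anyDuplicated(ids)) stop("duplicated component_id", call. = FALSE)
  mat <- df[, setdiff(names(df), "component_id"), drop = FALSE]
  for (col in names(mat)) mat[[col]] <- as.numeric(mat[[col]])
  if (any(!vapply(mat, function(v) all(is.finite(v)), logical(1)))) {
    stop("descriptor values must be finite", call. = FALSE)
  }
  rownames(mat) <- ids
  structure(mat, class = c("descriptor_table", "data.frame"))
}

#' Write a descriptor table to CSV
#' @param table a [descriptor_table()].
#' @param path output CSV path.
#' @export
write_descriptor_table <- function(table, path) {
  out <- cbind(component_id = rownames(table), as.data.frame(table))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Build the weighted-mixture design matrix
#'
#' Expands per-component descriptors into mixture descriptors, one row per
#' record. Method 1 produces only the `*_pmix` columns; Method 2 produces
#' both `*_pmix` and `*_nmix`. Three auxiliary candidate variables are
#' always appended: `temperature` (K) and the two halide indicator flags
#' `cl_flag`, `br_flag` (the anionic part of a salt HBA enters the model
#' only through these flags).
#'
#' @param dataset a [mixture_dataset()].
#' @param table a [descriptor_table()] covering every referenced component.
#' @param method `1` (pmix only) or `2` (pmix and nmix).
#' @return A `feature_matrix`: data frame of named candidate columns, rows
#'   aligned to (and named by) the dataset's `record_id`.
#' @export
build_features <- function(dataset, table, method = 1) {
  if (!method %in% c(1, 2)) stop("method must be 1 or 2", call. = FALSE)
  comp_ids <- unique(c(dataset$comp1_id, dataset$comp2_id))
  unknown <- setdiff(comp_ids, rownames(table))
  if (length(unknown) > 0) {
    stop("component id(s) not in descriptor table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  d1 <- as.matrix(table[dataset$comp1_id, , drop = FALSE])
  d2 <- as.matrix(table[dataset$comp2_id, , drop = FALSE])
  x1 <- dataset$x1; x2 <- dataset$x2
  pm <- x1 * d1 + x2 * d2
  colnames(pm) <- paste0(colnames(table), "_pmix")
  cols <- pm
  if (method == 2) {
    nm <- abs(x1 * d1 - x2 * d2)
    colnames(nm) <- paste0(colnames(table), "_nmix")
    cols <- cbind(pm, nm)
  }
  out <- as.data.frame(cols)
  out$temperature <- dataset$temperature_K
  out$cl_flag <- dataset$cl_flag
  out$br_flag <- dataset$br_flag
  rownames(out) <- dataset$record_id
  structure(out, method = method,
            class = c("feature_matrix", "data.frame"))
}

#' Prune near-constant and highly intercorrelated candidate columns
#'
#' First drops every column whose variance falls below `variance_cutoff`
#' (strict inequality), then scans column pairs in input order and drops
#' the later column of any pair with `|Pearson r| > correlation_cutoff`.
#' The earlier column of a correlated pair always survives, making the
#' filter deterministic and idempotent. The auxiliary columns
#' (`temperature`, `cl_flag`, `br_flag`) are exempted from the variance
#' rule only when `keep_constant_aux = TRUE`; they always take part in
#' correlation filtering like any other candidate.
#'
#' @param matrix a `feature_matrix` (or plain data frame) with >= 2 rows.
#' @param variance_cutoff drop a column iff `var < variance_cutoff`.
#' @param correlation_cutoff drop the later column iff `|r| > correlation_cutoff`.
#' @param keep_constant_aux keep constant auxiliary columns anyway.
#' @return The filtered matrix, same class, column subset in original order.
#' @export
filter_features <- function(matrix, variance_cutoff = 0.001,
                            correlation_cutoff = 0.95,
                            keep_constant_aux = FALSE) {
  if (nrow(matrix) < 2) stop("need at least 2 rows to filter", call. = FALSE)
  m <- as.matrix(as.data.frame(matrix))
  vars <- apply(m, 2, stats::var)
  keep <- vars >= variance_cutoff
  if (keep_constant_aux) keep[colnames(m) %in% AUX_COLUMNS] <- TRUE
  m <- m[, keep, drop = FALSE]
  if (ncol(m) > 1) {
    suppressWarnings(cc <- abs(stats::cor(m)))
    cc[is.na(cc)] <- 0  # zero-variance aux retained above
    drop <- rep(FALSE, ncol(m))
    for (j in 2:ncol(m)) {
      for (i in 1:(j - 1)) {
        if (!drop[i] && cc[i, j] > correlation_cutoff) { drop[j] <- TRUE; break }
      }
    }
    m <- m[, !drop, drop = FALSE]
  }
  out <- matrix[, colnames(m), drop = FALSE]
  structure(out, method = attr(matrix, "method"),
            class = c("feature_matrix", "data.frame"))
}

#' Export a feature matrix to CSV
#' @param matrix a `feature_matrix`.
#' @param path output CSV path.
#' @export
write_features <- function(matrix, path) {
  out <- cbind(record_id = rownames(matrix), as.data.frame(matrix))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
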