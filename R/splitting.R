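#' Seed/interval stepping selection
#'
#' Deterministic selection rule shared by the mixtures-out and
#' compounds-out splitting schemes: from an ordered list, take the
#' elements at 1-based positions `seed, seed + interval, seed + 2*interval,
#' ...`. A seed beyond the end of the list selects nothing.
#'
#' @param sorted_keys ordered vector of keys.
#' @param seed starting position (>= 1).
#' @param interval stride (>= 1).
#' @return The selected keys (possibly empty), in list order.
#' @export
select_by_seed_interval <- function(sorted_keys, seed, interval) {
  stopifnot(seed >= 1, interval >= 1)
  n <- length(sorted_keys)
  if (seed > n) return(sorted_keys[0])
  sorted_keys[seq(from = seed, to = n, by = interval)]
}

.new_split <- function(dataset, test_idx, scheme, seed, interval, selected) {
  all_ids <- dataset$record_id
  test_ids <- all_ids[test_idx]
  train_ids <- setdiff(all_ids, test_ids)
  if (length(train_ids) == 0 || length(test_ids) == 0) {
    stop(sprintf("degenerate %s split (seed=%d, interval=%d): empty %s set",
                 scheme, seed, interval,
                 if (length(train_ids) == 0) "training" else "test"),
         call. = FALSE)
  }
  structure(list(
    train_ids = train_ids,
    test_ids = test_ids,
    spec = list(scheme = scheme, seed = as.integer(seed),
                interval = as.integer(interval)),
    selected_keys = selected
  ), class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat(sprintf("data_split [%s, seed=%d, interval=%d]: %d train / %d test\n",
              x$spec$scheme, x$spec$seed, x$spec$interval,
              length(x$train_ids), length(x$test_ids)))
  invisible(x)
}

#' Mixtures-out (MO) data split
#'
#' Unique mixtures (pair + molar ratio, see [mixture_key()]) are sorted by
#' occurrence count descending (lexicographic ascending tie-break); the
#' mixtures selected by the (seed, interval) stepping rule contribute all
#' of their records to the test set, every other record to training. No
#' mixture ever spans both sides of the partition.
#'
#' @param dataset a [mixture_dataset()].
#' @param seed,interval stepping parameters, see [select_by_seed_interval()].
#' @return A `data_split` with `train_ids`, `test_ids`, `spec`,
#'   `selected_keys`.
#' @export
mo_split <- function(dataset, seed, interval) {
  occ <- occurrence_counts(dataset, by = "mixture")
  if (nrow(occ) < 2) stop("need >= 2 unique mixtures", call. = FALSE)
  selected <- select_by_seed_interval(occ$key, seed, interval)
  keys <- mixture_key(dataset)
  .new_split(dataset, which(keys %in% selected), "MO", seed, interval,
             list(mixtures = selected))
}

#' Compounds-out (CO) data split
#'
#' The (seed, interval) stepping rule is applied independently to the
#' occurrence-sorted list of unique component-1 chemicals (HBAs) and to the
#' component-2 list (HBDs); a chemical appearing in both roles is counted
#' per role. Every record containing a selected chemical in its role goes
#' to the test set, so selected chemicals never occur in training.
#'
#' @inheritParams mo_split
#' @return A `data_split`.
#' @export
co_split <- function(dataset, seed, interval) {
  occ1 <- occurrence_counts(dataset, by = "component1")
  occ2 <- occurrence_counts(dataset, by = "component2")
  if (nrow(occ1) < 2 || nrow(occ2) < 2) {
    stop("need >= 2 unique chemicals in each component role", call. = FALSE)
  }
  sel1 <- select_by_seed_interval(occ1$key, seed, interval)
  sel2 <- select_by_seed_interval(occ2$key, seed, interval)
  test_idx <- which(dataset$comp1_id %in% sel1 | dataset$comp2_id %in% sel2)
  .new_split(dataset, test_idx, "CO", seed, interval,
             list(component1 = sel1, component2 = sel2))
}

#' Enumerate all admissible (seed, interval) splits
#'
#' Tries every `1 <= seed <= max_seed`, `1 <= interval <= max_interval`
#' under the given scheme and keeps the splits that satisfy the set-size
#' constraints `|train| > |test|` and `|test| >= min_test_frac * |train|`.
#' Degenerate splits are silently skipped. Distinct specs producing
#' identical partitions (same test-id set) are collapsed to one, keeping
#' the lexicographically smallest (seed, interval).
#'
#' @param dataset a [mixture_dataset()].
#' @param scheme `"MO"` or `"CO"`.
#' @param max_seed,max_interval search bounds (default 6).
#' @param min_test_frac minimum test/train size ratio (default 0.15).
#' @return List of `data_split` objects (possibly empty).
#' @export
enumerate_valid_splits <- function(dataset, scheme = c("MO", "CO"),
                                   max_seed = 6, max_interval = 6,
                                   min_test_frac = 0.15) {
  scheme <- match.arg(scheme)
  splitter <- if (scheme == "MO") mo_split else co_split
  out <- list()
  seen <- character(0)
  for (seed in seq_len(max_seed)) {
    for (interval in seq_len(max_interval)) {
      sp <- tryCatch(splitter(dataset, seed, interval), error = function(e) NULL)
      if (is.null(sp)) next
      ntr <- length(sp$train_ids); nts <- length(sp$test_ids)
      if (!(ntr > nts && nts >= min_test_frac * ntr)) next
      sig <- paste(sort(sp$test_ids), collapse = "\r")
      if (sig %in% seen) next
      seen <- c(seen, sig)
      out[[length(out) + 1L]] <- sp
    }
  }
  out
}

#' Export a data split to CSV + JSON sidecar
#'
#' Writes a two-column CSV (`record_id`, `set`) and a JSON sidecar at
#' `paste0(path, ".json")` holding the spec and selected keys.
#'
#' @param split a `data_split`.
#' @param path output CSV path.
#' @export
write_split <- function(split, path) {
  df <- data.frame(
    record_id = c(split$train_ids, split$test_ids),
    set = c(rep("train", length(split$train_ids)),
            rep("test", length(split$test_ids)))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(spec = split$spec,
                            selected_keys = split$selected_keys),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Subset a dataset by a data split
#'
#' @param dataset a [mixture_dataset()].
#' @param split a `data_split`.
#' @param set `"train"` or `"test"`.
#' @return The corresponding [mixture_dataset()] subset (row order preserved).
#' @export
split_subset <- function(dataset, split, set = c("train", "test")) {
  set <- match.arg(set)
  ids <- if (set == "train") split$train_ids else split$test_ids
  out <- dataset[dataset$record_id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(dataset, "provenance"),
            class = c("mixture_dataset", "data.frame"))
}
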