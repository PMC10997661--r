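# Dataset loading, sanitization, and splitting.

#' Load a molecule dataset from CSV
#'
#' Reads a CSV with SMILES and target columns, canonicalizes SMILES,
#' drops unparseable entries, bond-less and single-atom molecules, and
#' resolves duplicates (removing canonical-SMILES groups whose targets
#' disagree). Multi-fragment SMILES (salts etc.) are kept but reported.
#'
#' @param path CSV file path.
#' @param task "classification" (targets in \{0,1\}) or "regression".
#' @param smiles_col,target_col,id_col column names; `id_col = NULL`
#'   autonumbers.
#' @return data.frame of class `molecule_dataset` with columns
#'   `id`, `smiles` (canonical), `target`, and attribute `task`.
#' @export
load_dataset <- function(path, task = c("classification", "regression"),
                         smiles_col = "smiles", target_col = "target",
                         id_col = NULL) {
  task <- match.arg(task)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(smiles_col, target_col), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  ids <- if (!is.null(id_col) && id_col %in% names(raw)) {
    as.character(raw[[id_col]])
  } else {
    sprintf("mol%04d", seq_len(nrow(raw)))
  }
  records <- data.frame(id = ids,
                        smiles = as.character(raw[[smiles_col]]),
                        target = as.numeric(raw[[target_col]]),
                        stringsAsFactors = FALSE)
  sanitize_records(records, task)
}

#' Sanitize molecule records
#'
#' @param records data.frame with columns id, smiles, target.
#' @param task task type.
#' @return `molecule_dataset` data.frame.
#' @export
sanitize_records <- function(records, task = c("classification",
                                               "regression")) {
  task <- match.arg(task)
  n_in <- nrow(records)
  infos <- parse_molecules(records$smiles)
  parse_ok <- !vapply(infos, is.null, logical(1))
  n_unparseable <- sum(!parse_ok)
  records <- records[parse_ok, , drop = FALSE]
  infos <- infos[parse_ok]
  too_small <- vapply(infos, function(m) m$n_atoms < 2 || m$n_bonds < 1,
                      logical(1))
  n_small <- sum(too_small)
  records <- records[!too_small, , drop = FALSE]
  infos <- infos[!too_small]
  n_multi <- sum(vapply(infos, function(m) m$n_fragments > 1, logical(1)))
  records$smiles <- vapply(infos, `[[`, character(1), "smiles")
  if (task == "classification" &&
      !all(records$target %in% c(0, 1))) {
    stop("classification targets must be 0/1", call. = FALSE)
  }
  records <- remove_conflicts(records, task)
  if (nrow(records) == 0) {
    stop("no molecules survived sanitization", call. = FALSE)
  }
  message(sprintf(
    "loaded %d record(s): dropped %d unparseable, %d bond-less/single-atom; %d multi-fragment kept; %d retained after duplicate/conflict resolution",
    n_in, n_unparseable, n_small, n_multi, nrow(records)))
  rownames(records) <- NULL
  structure(records, task = task,
            class = c("molecule_dataset", "data.frame"))
}

#' Collapse duplicates and remove conflicting records
#'
#' Groups records by canonical SMILES. Groups whose targets disagree
#' (for regression: differ by more than `tol`) are removed entirely;
#' consistent groups collapse to their first record.
#'
#' @param records data.frame with canonical `smiles` and `target` columns.
#' @param task task type.
#' @param tol regression target tolerance for conflict detection.
#' @return deduplicated data.frame.
#' @export
remove_conflicts <- function(records, task = c("classification",
                                               "regression"),
                             tol = 1e-9) {
  task <- match.arg(task)
  if (nrow(records) == 0) return(records)
  groups <- split(seq_len(nrow(records)), records$smiles)
  keep <- integer(0)
  for (g in groups) {
    targets <- records$target[g]
    conflict <- if (task == "classification") {
      length(unique(targets)) > 1
    } else {
      diff(range(targets)) > tol
    }
    if (!conflict) keep <- c(keep, g[1])
  }
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Train/validation/test splits with cross-validation folds
#'
#' A random test split at the requested fraction, then the remaining
#' records partitioned into `n_folds` cross-validation folds whose
#' validation sets are pairwise disjoint. The test set is shared by all
#' folds. Deterministic given `seed`.
#'
#' @param records a `molecule_dataset` (or data.frame with `id`).
#' @param test_fraction fraction held out for testing (0 < f < 1).
#' @param n_folds number of CV folds (>= 2).
#' @param seed integer master seed.
#' @return a `dataset_split`: list with `test_ids`, `train_folds`
#'   (list of `list(train, validation)` id vectors), `n_folds`, `seed`.
#' @export
make_splits <- function(records, test_fraction = 0.2, n_folds = 5, seed = 1) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 ||
      test_fraction >= 1) {
    stop("test_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (n_folds < 2) stop("n_folds must be >= 2", call. = FALSE)
  ids <- records$id
  n <- length(ids)
  if (n < n_folds + 1) stop("dataset too small for requested folds",
                            call. = FALSE)
  with_seed(seed, {
    shuffled <- sample(ids)
    n_test <- max(1L, round(n * test_fraction))
    test_ids <- sort(shuffled[seq_len(n_test)])
    rest <- shuffled[-seq_len(n_test)]
    fold_of <- rep(seq_len(n_folds), length.out = length(rest))
    train_folds <- lapply(seq_len(n_folds), function(k) {
      list(train = sort(rest[fold_of != k]),
           validation = sort(rest[fold_of == k]))
    })
    structure(list(test_ids = test_ids, train_folds = train_folds,
                   n_folds = n_folds, seed = as.integer(seed)),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> %d fold(s), %d test molecule(s), seed %d\n",
              x$n_folds, length(x$test_ids), x$seed))
  for (k in seq_along(x$train_folds)) {
    cat(sprintf("  fold %d: %d train / %d validation\n", k,
                length(x$train_folds[[k]]$train),
                length(x$train_folds[[k]]$validation)))
  }
  invisible(x)
}

#' Write a split manifest as JSON
#' @param split a `dataset_split`.
#' @param path output JSON path.
#' @export
write_split_manifest <- function(split, path) {
  jsonlite::write_json(
    list(seed = split$seed, n_folds = split$n_folds,
         test_ids = split$test_ids,
         folds = lapply(split$train_folds, function(f)
           list(train = f$train, validation = f$validation))),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a molecule dataset to CSV
#' @param records a `molecule_dataset`.
#' @param path output CSV path.
#' @export
write_dataset <- function(records, path) {
  utils::write.csv(as.data.frame(records)[, c("id", "smiles", "target")],
                   path, row.names = FALSE)
  invisible(path)
}
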