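# End-to-end experiment drivers tying the modules together.

#' Run a synthetic binding-logic experiment end to end
#'
#' Generates a labeled dataset for a built-in logic, builds the graph
#' representations, trains cross-validation folds for each requested
#' scheme, evaluates test predictive performance and attention
#' interpretation against the ground-truth masks, and (optionally) mines
#' potential substructures from the predicted positives of the test set.
#'
#' @param logic built-in logic name (see [builtin_logics()]).
#' @param schemes character vector of scheme labels, e.g. c("A", "A+J").
#' @param n_molecules dataset size.
#' @param seed master seed driving generation, splitting and training.
#' @param n_folds cross-validation folds in the split.
#' @param folds fold indices actually trained (default: first two).
#' @param config a [model_config()]; the task is forced to
#'   classification.
#' @param substructures run the potential-substructures pipeline on the
#'   predicted-positive test molecules of each scheme.
#' @param extraction an [extraction_config()] for the substructure step.
#' @return a named list per scheme with the trained `scheme_result`,
#'   interpretation summary, and substructure selection, plus the shared
#'   dataset, split and masks.
#' @export
run_logic_experiment <- function(logic = "3MR",
                                 schemes = c("A", "A+J"),
                                 n_molecules = 2000, seed = 1,
                                 n_folds = 5, folds = 1:2,
                                 config = model_config(
                                   embedding_dim = 32, epochs = 50,
                                   patience = 50, learning_rate = 5e-3,
                                   batch_size = 64),
                                 substructures = TRUE,
                                 extraction = extraction_config()) {
  config$task <- "classification"
  gen <- generate_dataset(logic, n_molecules, seed = seed)
  records <- gen$records
  reps_needed <- unique(unlist(lapply(schemes, parse_scheme)))
  graphs <- build_graphs(records$smiles, reps_needed)
  split <- make_splits(records, test_fraction = 0.2, n_folds = n_folds,
                       seed = seed)
  test_idx <- match(split$test_ids, records$id)
  out <- list()
  for (sch in schemes) {
    scheme <- parse_scheme(sch)
    prep <- prepare_scheme_graphs(graphs, scheme)
    sr <- train_scheme(records, prep, scheme, split, config, folds = folds)
    models <- lapply(sr$folds, `[[`, "model")
    interp <- evaluate_interpretation(
      models, records[test_idx, ], prep[test_idx], gen$masks)
    sub <- NULL
    if (substructures) {
      best <- models[[which.max(vapply(sr$folds, `[[`, numeric(1),
                                       "best_validation_metric"))]]
      pm <- predict_molecules(best, prep[test_idx], with_attention = TRUE)
      pos <- which(pm$prediction >= 0.5)
      att <- list()
      smi <- character(0)
      for (i in pos) {
        idx <- test_idx[i]
        norm <- lapply(pm$attention[[i]], minmax_normalize)
        mapped <- lapply(best$scheme, function(r)
          map_to_atoms(prep[[idx]][[r]], norm[[r]]))
        att[[records$id[idx]]] <- combine_graphs(mapped)
        smi[records$id[idx]] <- records$smiles[idx]
      }
      fs <- fragment_statistics(att, smi, extraction)
      sub <- list(statistics = fs,
                  selected = suppressWarnings(
                    select_potential_substructures(fs)))
    }
    out[[sch]] <- list(scheme_result = sr, interpretation = interp,
                       substructures = sub)
  }
  list(results = out, records = records, split = split,
       masks = gen$masks, logic = logic, seed = seed)
}

#' Does a fragment contain a three-membered ring?
#' @param smiles fragment SMILES vector.
#' @return logical vector.
#' @export
has_three_membered_ring <- function(smiles) {
  infos <- parse_molecules(smiles)
  vapply(infos, function(m) {
    !is.null(m) && any(vapply(m$rings, length, integer(1)) == 3)
  }, logical(1))
}

#' Read and validate a YAML run configuration
#'
#' Recognized keys: `dataset` (CSV path) or `logic` (built-in name),
#' `task`, `scheme`, `n_molecules`, `seed`, `n_folds`, `folds`, `output`,
#' and a `model` block of [model_config()] arguments plus an
#' `extraction` block of [extraction_config()] arguments. Unknown keys
#' are rejected.
#'
#' @param path YAML file.
#' @return validated configuration list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("dataset", "logic", "task", "scheme", "n_molecules", "seed",
               "n_folds", "folds", "output", "model", "extraction")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown run-config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(cfg$dataset) && is.null(cfg$logic)) {
    stop("run config needs either `dataset` or `logic`", call. = FALSE)
  }
  cfg$task <- cfg$task %||% "classification"
  cfg$scheme <- cfg$scheme %||% "A"
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$n_folds <- as.integer(cfg$n_folds %||% 5L)
  cfg$model <- do.call(model_config,
                       c(cfg$model %||% list(), list(task = cfg$task)))
  cfg$extraction <- do.call(extraction_config, cfg$extraction %||% list())
  parse_scheme(cfg$scheme)
  structure(cfg, class = "run_config")
}

#' Write a reproducibility manifest for a run
#'
#' @param path output JSON path.
#' @param config the run configuration used.
#' @param seed the master seed.
#' @param extra named list of additional fields.
#' @export
write_run_manifest <- function(path, config, seed, extra = list()) {
  manifest <- c(list(
    package = "redgraph",
    version = as.character(utils::packageVersion("redgraph")),
    seed = as.integer(seed),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
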