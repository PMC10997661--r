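# Attention post-processing and the three interpretation views.
#
# Pipeline per molecule: raw virtual-link attention per graph ->
# min-max normalization -> projection onto atoms through the atom_map
# (summing where several nodes cover an atom, then renormalizing) ->
# max-combination across the scheme's graphs.

#' Min-max normalize a weight vector to [0, 1]
#'
#' Constant vectors map to 0.5 everywhere (neutral importance).
#'
#' @param weights non-empty numeric vector.
#' @return vector in [0, 1].
#' @export
minmax_normalize <- function(weights) {
  if (length(weights) == 0) stop("empty weight vector", call. = FALSE)
  rng <- range(weights)
  if (rng[1] == rng[2]) return(rep(0.5, length(weights)))
  (weights - rng[1]) / (rng[2] - rng[1])
}

#' Project node attention onto atoms
#'
#' Each atom receives the sum of the attention of every node whose
#' atom_map covers it (atoms covered by no node receive 0); the resulting
#' atom vector is min-max normalized.
#'
#' @param graph a `molecular_graph`.
#' @param node_attention numeric vector, one weight per node.
#' @return atom-level vector in [0, 1], length `graph$n_atoms`.
#' @export
map_to_atoms <- function(graph, node_attention) {
  stopifnot(length(node_attention) == length(graph$atom_map))
  atom <- numeric(graph$n_atoms)
  for (k in seq_along(graph$atom_map)) {
    a <- graph$atom_map[[k]]
    atom[a] <- atom[a] + node_attention[k]
  }
  minmax_normalize(atom)
}

#' Combine mapped attention across graphs by elementwise maximum
#'
#' @param mapped list of equal-length atom-level vectors (or a single
#'   vector).
#' @return combined atom-level vector.
#' @export
combine_graphs <- function(mapped) {
  if (is.numeric(mapped)) return(mapped)
  stopifnot(is.list(mapped), length(mapped) >= 1)
  lens <- vapply(mapped, length, integer(1))
  if (length(unique(lens)) != 1) {
    stop("attention vectors have differing lengths", call. = FALSE)
  }
  do.call(pmax, mapped)
}

#' Atom-level attention for one molecule under a model
#'
#' Runs the full interpretation extraction: forward pass, per-graph
#' min-max normalization of the raw readout attention, projection onto
#' atoms, and max-combination across the scheme's graphs.
#'
#' @param model a `redgraph_model`.
#' @param graphs_one prepared named graph list for one molecule.
#' @return an `attention_result`: prediction, per-representation raw and
#'   normalized node attention, per-representation mapped atom vectors,
#'   and the combined atom vector.
#' @export
attention_result <- function(model, graphs_one) {
  fwd <- forward_model(model, graphs_one)
  norm <- lapply(fwd$attention, minmax_normalize)
  mapped <- lapply(model$scheme, function(r)
    map_to_atoms(graphs_one[[r]], norm[[r]]))
  names(mapped) <- model$scheme
  structure(list(
    prediction = fwd$prediction,
    raw_attention = fwd$attention,
    node_attention = norm,
    atom_attention = mapped,
    combined = combine_graphs(mapped),
    smiles = graphs_one[[1]]$smiles
  ), class = "attention_result")
}

#' Fold-averaged combined atom attention
#'
#' Per-fold combined vectors (each fold normalized on its own) averaged
#' arithmetically.
#'
#' @param models list of fold models (same scheme).
#' @param graphs_one prepared named graph list for one molecule.
#' @return list with `combined` (averaged atom vector), `per_fold`
#'   (matrix folds x atoms) and `prediction` (mean prediction).
#' @export
fold_attention <- function(models, graphs_one) {
  res <- lapply(models, attention_result, graphs_one = graphs_one)
  per_fold <- do.call(rbind, lapply(res, `[[`, "combined"))
  list(combined = colMeans(per_fold), per_fold = per_fold,
       prediction = mean(vapply(res, `[[`, numeric(1), "prediction")))
}

#' Single-prediction view: depiction plus numeric dump
#'
#' Renders the molecule with per-atom green highlight intensity
#' proportional to the combined attention (SVG), and writes the numeric
#' vector as JSON.
#'
#' @param smiles molecule SMILES (canonical ordering is used for atoms).
#' @param combined atom-level combined attention vector.
#' @param out_prefix output path prefix; writes `<prefix>.svg` and
#'   `<prefix>.json`.
#' @return invisibly, the list of files written.
#' @export
single_prediction_view <- function(smiles, combined, out_prefix) {
  json_path <- paste0(out_prefix, ".json")
  jsonlite::write_json(list(smiles = smiles,
                            attention = as.numeric(combined)),
                       json_path, auto_unbox = TRUE, digits = NA)
  files <- json_path
  svg <- tryCatch(depict_svg(smiles, combined), error = function(e) NULL)
  if (is.null(svg)) {
    warning("depiction failed; numeric output only", call. = FALSE)
  } else {
    svg_path <- paste0(out_prefix, ".svg")
    writeLines(svg, svg_path)
    files <- c(files, svg_path)
  }
  invisible(files)
}

#' Node-features view: attention per node-feature over a dataset
#'
#' For every indicator node feature active in the (optionally filtered)
#' molecule set, accumulates that node's per-graph normalized attention,
#' averaged across fold models; reports the mean attention and occurrence
#' count per feature and representation. Multi-hot nodes contribute to
#' every active feature name.
#'
#' @param models list of fold models (same scheme).
#' @param graphs per-molecule prepared graphs.
#' @param filter optional logical vector or function of the fold-mean
#'   predictions selecting molecules (e.g. `function(p) p > -2`).
#' @return a `node_feature_summary` data.frame (representation, feature,
#'   mean_attention, count).
#' @export
node_features_view <- function(models, graphs, filter = NULL) {
  scheme <- models[[1]]$scheme
  preds <- rowMeans(vapply(models, function(m)
    predict_molecules(m, graphs), numeric(length(graphs))))
  keep <- rep(TRUE, length(graphs))
  if (is.function(filter)) keep <- filter(preds)
  if (is.logical(filter)) keep <- filter
  if (!any(keep)) stop("no molecules pass the prediction filter",
                       call. = FALSE)
  graphs <- graphs[keep]
  rows <- list()
  for (r in scheme) {
    att_by_fold <- lapply(models, function(m) {
      pm <- predict_molecules(m, graphs, with_attention = TRUE)
      lapply(pm$attention, function(a) minmax_normalize(a[[r]]))
    })
    sums <- list()
    counts <- list()
    for (i in seq_along(graphs)) {
      g <- graphs[[i]][[r]]
      att <- rowMeans(vapply(att_by_fold, function(f) f[[i]],
                             numeric(nrow(g$node_features))))
      for (k in seq_len(nrow(g$node_features))) {
        active <- colnames(g$node_features)[g$node_features[k, ] == 1]
        for (feat in active) {
          sums[[feat]] <- (sums[[feat]] %||% 0) + att[k]
          counts[[feat]] <- (counts[[feat]] %||% 0L) + 1L
        }
      }
    }
    if (length(counts) > 0) {
      rows[[r]] <- data.frame(
        representation = r,
        feature = names(counts),
        mean_attention = vapply(names(counts), function(f)
          sums[[f]] / counts[[f]], numeric(1)),
        count = vapply(names(counts), function(f) counts[[f]],
                       integer(1)),
        row.names = NULL)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("node_feature_summary", "data.frame")
  out
}

#' Scatter plot of a node-feature summary
#'
#' Mean attention versus occurrence count per node feature; significant
#' features sit in the top-right region.
#'
#' @param summary a `node_feature_summary` from [node_features_view()].
#' @return a ggplot object.
#' @export
plot_node_features <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = count, y = mean_attention,
                               colour = representation,
                               label = feature)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "number of feature nodes",
                  y = "mean node attention",
                  colour = "graph") +
    ggplot2::theme_minimal()
}

#' Correlation of attention between two representations
#'
#' Per molecule, the rank (Spearman) correlation between two
#' representations' mapped atom-level attention vectors; molecules with
#' fewer than three atoms or a constant vector are skipped.
#'
#' @param model a `redgraph_model` with at least two representations.
#' @param graphs per-molecule prepared graphs.
#' @param reps the two representations to compare (default: first two of
#'   the scheme).
#' @return list with `per_molecule` (data.frame) and `summary`
#'   (mean/median/sd of the per-molecule correlations).
#' @export
attention_correlation <- function(model, graphs, reps = NULL) {
  if (length(model$scheme) < 2) {
    stop("attention correlation needs a scheme with >= 2 representations",
         call. = FALSE)
  }
  if (is.null(reps)) reps <- model$scheme[1:2]
  stopifnot(length(reps) == 2, all(reps %in% model$scheme))
  cors <- rep(NA_real_, length(graphs))
  for (i in seq_along(graphs)) {
    res <- attention_result(model, graphs[[i]])
    v1 <- res$atom_attention[[reps[1]]]
    v2 <- res$atom_attention[[reps[2]]]
    if (length(v1) < 3 || stats::sd(v1) == 0 || stats::sd(v2) == 0) next
    cors[i] <- stats::cor(v1, v2, method = "spearman")
  }
  pm <- data.frame(molecule = seq_along(graphs), correlation = cors)
  ok <- pm$correlation[!is.na(pm$correlation)]
  list(per_molecule = pm,
       summary = c(mean = mean(ok), median = stats::median(ok),
                   sd = stats::sd(ok), n = length(ok)))
}
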