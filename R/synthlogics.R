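# Synthetic binding-logic benchmarks: boolean SMARTS logics with
# atom-level ground truth, a molecule generator, and the attention
# evaluation metrics (attention AUROC / attention accuracy).

#' Logic expression constructors
#'
#' A logic is a boolean tree whose leaves are SMARTS patterns; a molecule
#' is positive iff the tree evaluates true under substructure matching.
#'
#' @param smarts SMARTS pattern string.
#' @param ... child expressions.
#' @param x child expression.
#' @return logic expression nodes.
#' @name logic-expressions
NULL

#' @rdname logic-expressions
#' @export
logic_leaf <- function(smarts) {
  stopifnot(is.character(smarts), length(smarts) == 1)
  structure(list(op = "leaf", smarts = smarts), class = "logic_expr")
}

#' @rdname logic-expressions
#' @export
logic_and <- function(...) {
  structure(list(op = "and", args = list(...)), class = "logic_expr")
}

#' @rdname logic-expressions
#' @export
logic_or <- function(...) {
  structure(list(op = "or", args = list(...)), class = "logic_expr")
}

#' @rdname logic-expressions
#' @export
logic_not <- function(x) {
  structure(list(op = "not", args = list(x)), class = "logic_expr")
}

logic_leaves <- function(expr) {
  if (expr$op == "leaf") return(expr$smarts)
  unlist(lapply(expr$args, logic_leaves))
}

#' Define a synthetic binding logic
#'
#' @param name logic name.
#' @param expression a `logic_expr` tree.
#' @param positive_patterns SMARTS leaves whose matched atoms constitute
#'   the ground truth for positive molecules (never leaves under NOT).
#' @return a `logic_spec`.
#' @export
logic_spec <- function(name, expression, positive_patterns) {
  stopifnot(inherits(expression, "logic_expr"))
  leaves <- unique(logic_leaves(expression))
  stopifnot(all(positive_patterns %in% leaves))
  structure(list(name = name, expression = expression,
                 leaves = leaves,
                 positive_patterns = positive_patterns),
            class = "logic_spec")
}

#' @export
print.logic_spec <- function(x, ...) {
  cat(sprintf("<logic_spec> %s: %d leaf pattern(s), %d ground-truth pattern(s)\n",
              x$name, length(x$leaves), length(x$positive_patterns)))
  invisible(x)
}

#' The five built-in binding logics
#'
#' Boolean combinations of SMARTS substructures defining the synthetic
#' benchmark tasks: fluorine plus carbonyl; unbranched acyclic chain plus
#' carbonyl; primary amine plus dialkyl ether plus mono-substituted
#' benzene; (ether or no hydroxyl) plus carbonyl and no internal alkyne;
#' and any three-membered ring.
#'
#' @return named list of `logic_spec`s.
#' @export
builtin_logics <- function() {
  carbonyl <- "[CX3]=O"
  logics <- list(
    Logic6 = logic_spec(
      "Logic6",
      logic_and(logic_leaf("[FX1]"), logic_leaf(carbonyl)),
      c("[FX1]", carbonyl)),
    Logic7 = logic_spec(
      "Logic7",
      logic_and(logic_leaf("[R0;D2,D1][R0;D2][R0;D2,D1]"),
                logic_leaf(carbonyl)),
      c("[R0;D2,D1][R0;D2][R0;D2,D1]", carbonyl)),
    Logic9 = logic_spec(
      "Logic9",
      logic_and(logic_leaf("[NX3;H2]"), logic_leaf("[OD2](C)C"),
                logic_leaf("[cX3]1[cX3H][cX3H][cX3H][cX3H][cX3H]1")),
      c("[NX3;H2]", "[OD2](C)C",
        "[cX3]1[cX3H][cX3H][cX3H][cX3H][cX3H]1")),
    Logic14 = logic_spec(
      "Logic14",
      logic_and(
        logic_or(logic_leaf("[OD2](C)C"), logic_not(logic_leaf("[OX2H]"))),
        logic_leaf(carbonyl),
        logic_not(logic_leaf("[CX2]#[CX2]"))),
      c("[OD2](C)C", carbonyl)),
    `3MR` = logic_spec("3MR", logic_leaf("*1**1"), "*1**1")
  )
  logics
}

eval_expr <- function(expr, has) {
  switch(expr$op,
         leaf = has[[expr$smarts]],
         and = all(vapply(expr$args, eval_expr, logical(1), has = has)),
         or = any(vapply(expr$args, eval_expr, logical(1), has = has)),
         not = !eval_expr(expr$args[[1]], has))
}

mask_alternatives <- function(spec, matches, cap = 32L) {
  contributing <- list()
  for (p in spec$positive_patterns) {
    if (length(matches[[p]]) > 0) {
      contributing[[p]] <- unique(lapply(matches[[p]], sort))
    }
  }
  if (length(contributing) == 0) return(list())
  counts <- vapply(contributing, length, integer(1))
  combos <- expand.grid(lapply(counts, seq_len), KEEP.OUT.ATTRS = FALSE)
  if (nrow(combos) > cap) combos <- combos[seq_len(cap), , drop = FALSE]
  masks <- lapply(seq_len(nrow(combos)), function(k) {
    sort(unique(unlist(lapply(seq_along(contributing), function(j)
      contributing[[j]][[combos[k, j]]]))))
  })
  unique(masks)
}

#' Evaluate a logic on molecules
#'
#' @param spec a `logic_spec`.
#' @param smiles character vector of SMILES.
#' @param cap maximum number of ground-truth alternatives per molecule.
#' @return list with `labels` (0/1 vector; NA for unparseable SMILES) and
#'   `masks` (per molecule, a list of alternative atom-index sets; empty
#'   for negatives).
#' @export
evaluate_logic <- function(spec, smiles, cap = 32L) {
  ms <- match_smarts(smiles, spec$leaves)
  labels <- integer(length(smiles))
  masks <- vector("list", length(smiles))
  for (i in seq_along(smiles)) {
    if (is.null(ms[[i]])) {
      labels[i] <- NA_integer_
      masks[[i]] <- list()
      next
    }
    has <- lapply(ms[[i]], function(m) length(m) > 0)
    lab <- eval_expr(spec$expression, has)
    labels[i] <- as.integer(lab)
    masks[[i]] <- if (lab) mask_alternatives(spec, ms[[i]], cap) else list()
  }
  list(labels = labels, masks = masks)
}

# --- generator --------------------------------------------------------------

#' Generator configuration for synthetic datasets
#'
#' The generator assembles drug-like molecules (default 8-25 heavy atoms)
#' from a fragment grammar of chain, branch and ring units, inserting or
#' withholding the logic's pattern pieces to steer the class balance
#' toward 50/50.
#'
#' @param min_units,max_units number of backbone units per molecule.
#' @param max_rounds candidate-generation rounds before accepting an
#'   unbalanced dataset.
#' @param piece_prob probability that a positive-aimed molecule receives
#'   each pattern piece.
#' @return a `generator_config` list.
#' @export
generator_config <- function(min_units = 3, max_units = 7, max_rounds = 20,
                             piece_prob = 0.95) {
  structure(list(min_units = min_units, max_units = max_units,
                 max_rounds = max_rounds, piece_prob = piece_prob),
            class = "generator_config")
}

# inline units keep a free valence on both sides; terminal units close a
# chain end. The "plain" alphabet yields linear, pattern-prone backbones;
# the "dense" alphabet yields branched/cyclic backbones used to steer
# negatives for chain-based logics.
GEN_UNITS <- list(
  plain_inline = c("C", "CC", "CCC", "O", "N", "C(C)", "C(=O)", "S",
                   "c1ccc(cc1)", "C1CCC(CC1)"),
  dense_inline = c("C(C)(C)", "c1ccc(cc1)", "C1CCC(CC1)", "N(C)", "O",
                   "C(C)(C)C(C)(C)"),
  terminal = c("C", "CC", "C(C)C", "c1ccccc1", "C1CCCCC1", "O", "N(C)C")
)

# negative_alphabet = "dense" only where the logic's pattern arises
# spontaneously in plain linear backbones (the unbranched-chain logic);
# piece-based logics keep the same backbone distribution in both classes
# so that the pattern pieces remain the only systematic class signal.
logic_pieces <- function(name) {
  switch(name,
    Logic6 = list(inline = c("C(=O)"), terminal = c("F"),
                  negative_alphabet = "plain"),
    Logic7 = list(inline = c("C(=O)"), terminal = c("CCC"),
                  negative_alphabet = "dense"),
    Logic9 = list(inline = c("COC"), terminal = c("N", "c1ccccc1"),
                  negative_alphabet = "plain"),
    Logic14 = list(inline = c("C(=O)", "COC"), terminal = character(0),
                   avoid_terminal = c("O", "C#C"),
                   negative_alphabet = "plain"),
    `3MR` = list(inline = c("C1CC1"), terminal = c("C1CC1"),
                 negative_alphabet = "plain"),
    list(inline = character(0), terminal = character(0),
         negative_alphabet = "plain")
  )
}

assemble_smiles <- function(aim_positive, pieces, gcfg) {
  alphabet <- if (aim_positive ||
                    identical(pieces$negative_alphabet, "plain")) {
    GEN_UNITS$plain_inline
  } else {
    GEN_UNITS$dense_inline
  }
  n_units <- sample(gcfg$min_units:gcfg$max_units, 1)
  units <- sample(alphabet, n_units, replace = TRUE)
  if (aim_positive) {
    for (pc in pieces$inline) {
      if (stats::runif(1) < gcfg$piece_prob) {
        pos <- sample(seq_len(length(units) + 1) - 1, 1)
        units <- append(units, pc, after = pos)
      }
    }
  } else {
    # negatives occasionally carry a random subset of the pieces so the
    # label is decided by the full logic, not by piece presence alone
    for (pc in c(pieces$inline, pieces$terminal)) {
      if (stats::runif(1) < 0.15) {
        units <- append(units, pc, after = sample(length(units), 1))
      }
    }
  }
  tail_units <- character(0)
  if (aim_positive) {
    for (pc in pieces$terminal) {
      if (stats::runif(1) < gcfg$piece_prob) tail_units <- c(tail_units, pc)
    }
  } else if (!is.null(pieces$avoid_terminal) && stats::runif(1) < 0.5) {
    # a NOT-clause trigger placed at the true chain end
    tail_units <- sample(pieces$avoid_terminal, 1)
  }
  if (length(tail_units) == 0) tail_units <- sample(GEN_UNITS$terminal, 1)
  # first terminal piece closes the main chain; extras become branches
  smi <- paste0(paste(units, collapse = ""), tail_units[1])
  if (length(tail_units) > 1) {
    branches <- paste0("(", tail_units[-1], ")", collapse = "")
    smi <- paste0("C", branches, smi)
  }
  smi
}

#' Generate a labeled synthetic binding-logic dataset
#'
#' Molecules are assembled from a fragment grammar, labeled by the exact
#' logic evaluation, and sampled to an (approximately) balanced dataset.
#' Deterministic given `seed`.
#'
#' @param spec a `logic_spec` or a built-in logic name.
#' @param n_molecules dataset size (>= 100).
#' @param seed integer seed.
#' @param gcfg a [generator_config()].
#' @return list with `records` (a `molecule_dataset`) and `masks` (named
#'   per-molecule ground-truth alternatives).
#' @export
generate_dataset <- function(spec, n_molecules = 2000, seed = 1,
                             gcfg = generator_config()) {
  if (is.character(spec)) {
    logics <- builtin_logics()
    if (!spec %in% names(logics)) {
      stop("unknown logic '", spec, "'; built-ins: ",
           paste(names(logics), collapse = ", "), call. = FALSE)
    }
    spec <- logics[[spec]]
  }
  stopifnot(inherits(spec, "logic_spec"), n_molecules >= 100)
  pieces <- logic_pieces(spec$name)
  target_per_class <- ceiling(n_molecules / 2)
  pos <- character(0)
  neg <- character(0)
  with_seed(seed, {
    for (round in seq_len(gcfg$max_rounds)) {
      need_pos <- target_per_class - length(pos)
      need_neg <- target_per_class - length(neg)
      if (need_pos <= 0 && need_neg <= 0) break
      n_cand <- max(200L, 2L * max(need_pos, need_neg))
      aim <- stats::runif(n_cand) < (need_pos / (need_pos + need_neg + 1e-9))
      cand <- vapply(aim, assemble_smiles, character(1), pieces = pieces,
                     gcfg = gcfg)
      canon <- canonical_smiles(cand)
      ok <- !is.na(canon) & !duplicated(canon) &
        !(canon %in% pos) & !(canon %in% neg)
      canon <- canon[ok]
      if (length(canon) == 0) next
      infos <- parse_molecules(canon)
      sizes <- vapply(infos, function(m) m$n_atoms, integer(1))
      nb <- vapply(infos, function(m) m$n_bonds, integer(1))
      canon <- canon[sizes >= 4 & sizes <= 30 & nb >= 1]
      if (length(canon) == 0) next
      ev <- evaluate_logic(spec, canon)
      pos <- c(pos, canon[ev$labels == 1])[seq_len(
        min(target_per_class, length(pos) + sum(ev$labels == 1)))]
      neg <- c(neg, canon[ev$labels == 0])[seq_len(
        min(target_per_class, length(neg) + sum(ev$labels == 0)))]
    }
    if (length(pos) < target_per_class || length(neg) < target_per_class) {
      warning(sprintf(
        "class balance unreachable: %d positive / %d negative generated",
        length(pos), length(neg)), call. = FALSE)
    }
    smiles <- c(pos, neg)[sample(length(pos) + length(neg))]
    smiles <- smiles[seq_len(min(n_molecules, length(smiles)))]
    ev <- evaluate_logic(spec, smiles)
    ids <- sprintf("%s_%05d", gsub("[^A-Za-z0-9]", "", spec$name),
                   seq_along(smiles))
    records <- structure(
      data.frame(id = ids, smiles = smiles, target = ev$labels,
                 stringsAsFactors = FALSE),
      task = "classification",
      class = c("molecule_dataset", "data.frame"))
    names(ev$masks) <- ids
    list(records = records, masks = ev$masks, spec = spec)
  })
}

# --- attention evaluation metrics -------------------------------------------

auroc_rank <- function(score, label) {
  # Mann-Whitney formulation with average ranks (exact AUROC under ties)
  pos <- label == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Attention AUROC against ground-truth masks
#'
#' The AUROC of the atom attention as a scorer of mask membership; with
#' several alternative ground truths, the maximum over masks is returned.
#' Masks covering no atom or every atom are undefined and skipped.
#'
#' @param attention atom-level attention vector.
#' @param masks list of alternative ground-truth atom-index sets.
#' @return scalar AUROC, or NA when undefined for every mask.
#' @export
attention_auroc <- function(attention, masks) {
  if (length(attention) == 0) stop("empty attention vector", call. = FALSE)
  vals <- vapply(masks, function(m) {
    y <- as.integer(seq_along(attention) %in% m)
    if (all(y == 1) || all(y == 0)) return(NA_real_)
    auroc_rank(attention, y)
  }, numeric(1))
  if (all(is.na(vals))) return(NA_real_)
  max(vals, na.rm = TRUE)
}

#' Attention accuracy against ground-truth masks
#'
#' Atoms with attention at or above 0.5 are predicted important; the
#' accuracy against mask membership is computed per mask and the maximum
#' over alternative masks returned.
#'
#' @inheritParams attention_auroc
#' @return scalar accuracy in [0, 1].
#' @export
attention_acc <- function(attention, masks) {
  if (length(attention) == 0) stop("empty attention vector", call. = FALSE)
  if (length(masks) == 0) return(NA_real_)
  yhat <- as.integer(attention >= 0.5)
  max(vapply(masks, function(m) {
    y <- as.integer(seq_along(attention) %in% m)
    mean(yhat == y)
  }, numeric(1)))
}

#' Interpretation performance of fold models on a logic dataset
#'
#' Restricted to true positives (label 1 and predicted probability at or
#' above 0.5 by the fold model), computes the per-fold mean attention
#' AUROC and attention accuracy of the combined atom attention, then the
#' mean and standard deviation across folds.
#'
#' @param models list of fold models (same scheme).
#' @param records `molecule_dataset` of the evaluated molecules.
#' @param graphs prepared graphs aligned with `records`.
#' @param masks named list (by record id) of ground-truth alternatives.
#' @return list with `per_fold` data.frame and `summary` data.frame
#'   (metric, mean, sd).
#' @export
evaluate_interpretation <- function(models, records, graphs, masks) {
  per_fold <- list()
  for (k in seq_along(models)) {
    model <- models[[k]]
    pm <- predict_molecules(model, graphs, with_attention = TRUE)
    tp <- which(records$target == 1 & pm$prediction >= 0.5)
    if (length(tp) == 0) {
      stop("fold ", k, ": no true-positive predictions", call. = FALSE)
    }
    aucs <- numeric(0); accs <- numeric(0)
    for (i in tp) {
      mk <- masks[[records$id[i]]]
      if (length(mk) == 0) next
      norm <- lapply(pm$attention[[i]], minmax_normalize)
      mapped <- lapply(model$scheme, function(r)
        map_to_atoms(graphs[[i]][[r]], norm[[r]]))
      combined <- combine_graphs(mapped)
      au <- attention_auroc(combined, mk)
      ac <- attention_acc(combined, mk)
      if (!is.na(au)) aucs <- c(aucs, au)
      if (!is.na(ac)) accs <- c(accs, ac)
    }
    per_fold[[k]] <- data.frame(fold = k, n_true_positive = length(tp),
                                att_auroc = mean(aucs),
                                att_acc = mean(accs))
  }
  pf <- do.call(rbind, per_fold)
  summary <- data.frame(
    metric = c("AttAUROC", "AttACC"),
    mean = c(mean(pf$att_auroc), mean(pf$att_acc)),
    sd = c(stats::sd(pf$att_auroc), stats::sd(pf$att_acc)))
  list(per_fold = pf, summary = summary)
}
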