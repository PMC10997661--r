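# The four molecular graph representations.
#
# Every representation is expressed as a `molecular_graph`: a node-feature
# matrix, an undirected edge list, and an explicit atom_map giving, for each
# node, the atom indices of the source atom-level graph it covers. The
# atom_map is what later lets readout attention be projected back onto
# atoms.

new_molecular_graph <- function(representation, smiles, n_atoms,
                                node_features, edges, edge_features,
                                atom_map, feature_names) {
  stopifnot(is.matrix(node_features),
            nrow(node_features) == length(atom_map))
  if (nrow(edges) > 0) {
    stopifnot(max(edges) <= nrow(node_features), min(edges) >= 1)
  }
  structure(list(
    representation = representation,
    smiles = smiles,
    n_atoms = n_atoms,
    node_features = node_features,
    edges = edges,
    edge_features = edge_features,
    atom_map = lapply(atom_map, function(a) sort(as.integer(a))),
    feature_names = feature_names
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph %s> %s\n  %d node(s), %d edge(s), %d atom(s)\n",
              x$representation, x$smiles, nrow(x$node_features),
              nrow(x$edges), x$n_atoms))
  invisible(x)
}

as_mol_info <- function(x) {
  if (inherits(x, "mol_info")) return(x)
  if (is.character(x) && length(x) == 1) {
    info <- parse_molecules(x)[[1]]
    if (is.null(info)) stop("unparseable SMILES: ", x, call. = FALSE)
    return(info)
  }
  stop("expected a SMILES string or mol_info", call. = FALSE)
}

# Undirected node-node edges for reduced graphs: two nodes are linked when
# their atom sets overlap or some molecular bond connects them.
group_edges <- function(atom_map, bonds, n_atoms) {
  n_nodes <- length(atom_map)
  if (n_nodes <= 1) return(matrix(integer(0), ncol = 2))
  owner <- vector("list", n_atoms)
  for (k in seq_len(n_nodes)) {
    for (a in atom_map[[k]]) owner[[a]] <- c(owner[[a]], k)
  }
  pairs <- list()
  add_pairs <- function(ks) {
    ks <- unique(ks)
    if (length(ks) >= 2) {
      cmb <- utils::combn(sort(ks), 2)
      pairs[[length(pairs) + 1]] <<- t(cmb)
    }
  }
  for (a in seq_len(n_atoms)) add_pairs(owner[[a]])
  if (nrow(bonds) > 0) {
    for (b in seq_len(nrow(bonds))) {
      k1 <- owner[[bonds$a1[b]]]
      k2 <- owner[[bonds$a2[b]]]
      for (i in k1) for (j in k2) if (i != j) {
        pairs[[length(pairs) + 1]] <- matrix(c(min(i, j), max(i, j)), ncol = 2)
      }
    }
  }
  if (length(pairs) == 0) return(matrix(integer(0), ncol = 2))
  e <- unique(do.call(rbind, pairs))
  e[order(e[, 1], e[, 2]), , drop = FALSE]
}

order_nodes <- function(atom_map) {
  mins <- vapply(atom_map, min, numeric(1))
  sizes <- vapply(atom_map, length, numeric(1))
  maxs <- vapply(atom_map, max, numeric(1))
  order(mins, sizes, maxs)
}

reindex_graph <- function(atom_map, features, ord) {
  perm <- match(seq_along(ord), ord)  # old index -> new index
  list(atom_map = atom_map[ord], features = features[ord, , drop = FALSE],
       perm = perm)
}

# --- Atom graph -------------------------------------------------------------

#' Build the atom-level molecular graph
#'
#' Nodes are heavy atoms with element/degree/charge/aromaticity/
#' hybridization/H-count/ring features; edges are bonds with bond-type/
#' conjugation/ring features.
#'
#' @param x a SMILES string or a parsed `mol_info`.
#' @return a `molecular_graph` with representation "A".
#' @export
build_atom_graph <- function(x) {
  info <- as_mol_info(x)
  vocab <- feature_vocabulary("A")
  at <- info$atoms
  n <- info$n_atoms
  feats <- t(vapply(seq_len(n), function(i) {
    c(one_hot(at$element[i], ELEMENTS),
      one_hot(min(at$degree[i], 5L), as.character(0:5)),
      at$charge[i],
      as.numeric(at$aromatic[i]),
      one_hot(at$hybridization[i], HYBRIDIZATIONS),
      one_hot(min(at$num_h[i], 4L), as.character(0:4)),
      as.numeric(at$in_ring[i]))
  }, numeric(vocab$node_width)))
  colnames(feats) <- vocab$node_features
  bd <- info$bonds
  if (nrow(bd) > 0) {
    efeats <- t(vapply(seq_len(nrow(bd)), function(b) {
      c(one_hot(as.character(bd$order[b]), as.character(1:4)),
        as.numeric(bd$conjugated[b]),
        as.numeric(bd$in_ring[b]))
    }, numeric(vocab$edge_width)))
    colnames(efeats) <- vocab$edge_features
    edges <- cbind(pmin(bd$a1, bd$a2), pmax(bd$a1, bd$a2))
  } else {
    efeats <- matrix(numeric(0), ncol = vocab$edge_width)
    edges <- matrix(integer(0), ncol = 2)
  }
  new_molecular_graph("A", info$smiles, n, feats, edges, efeats,
                      as.list(seq_len(n)), vocab$node_features)
}

# --- Pharmacophore graph ----------------------------------------------------

pharm_atom_flags <- function(info, matches) {
  n <- info$n_atoms
  flags <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, names(matches)))
  for (cls in names(matches)) {
    for (m in matches[[cls]]) flags[m, cls] <- TRUE
  }
  flags
}

#' Build the pharmacophore reduced graph
#'
#' An ErG-style reduction: each smallest ring collapses to one node (typed
#' aromatic and/or hydrophobic), acyclic atoms with pharmacophoric character
#' become typed feature nodes, maximal acyclic carbon chains of three or
#' more untyped atoms collapse to one hydrophobic node, and remaining
#' typeless atoms stay as untyped linker nodes so topology is preserved.
#'
#' @param x SMILES string or `mol_info`.
#' @param definitions pharmacophore SMARTS definitions
#'   (see [pharmacophore_definitions()]).
#' @param matches optional precomputed per-class atom matches (internal,
#'   used by the batched builder).
#' @return a `molecular_graph` with representation "P".
#' @export
build_pharmacophore_graph <- function(x,
                                      definitions = pharmacophore_definitions(),
                                      matches = NULL) {
  info <- as_mol_info(x)
  vocab <- feature_vocabulary("P")
  if (is.null(matches)) {
    all_smarts <- unlist(definitions, use.names = FALSE)
    raw <- match_smarts(info$smiles, all_smarts)[[1]]
    matches <- split_pharm_matches(raw, definitions)
  }
  flags <- pharm_atom_flags(info, matches)
  n <- info$n_atoms
  at <- info$atoms
  in_any_ring <- at$in_ring
  atom_map <- list()
  feats <- list()

  add_node <- function(atoms, bits, ring) {
    atom_map[[length(atom_map) + 1]] <<- atoms
    feats[[length(feats) + 1]] <<- c(bits, as.numeric(ring), length(atoms))
  }
  pbits <- function(atoms) {
    b <- numeric(6)
    names(b) <- PHARM_CLASSES
    sub <- flags[atoms, , drop = FALSE]
    b["donor"] <- as.numeric(any(sub[, "donor"]))
    b["acceptor"] <- as.numeric(any(sub[, "acceptor"]))
    b["positive"] <- as.numeric(any(sub[, "positive"]))
    b["negative"] <- as.numeric(any(sub[, "negative"]))
    b
  }

  # ring nodes
  for (ring in info$rings) {
    b <- pbits(ring)
    b["aromatic"] <- as.numeric(all(at$aromatic[ring]))
    b["hydrophobic"] <- as.numeric(all(at$element[ring] == "C") &&
                                     !b["aromatic"])
    add_node(ring, b, TRUE)
  }

  acyclic <- which(!in_any_ring)
  typed <- acyclic[rowSums(flags[acyclic, , drop = FALSE]) > 0]
  for (a in typed) add_node(a, pbits(a), FALSE)

  # untyped acyclic atoms: carbon chains of >= 3 collapse to hydrophobic
  untyped <- setdiff(acyclic, typed)
  uc <- untyped[at$element[untyped] == "C"]
  if (length(uc) > 0) {
    sub_bonds <- info$bonds[info$bonds$a1 %in% uc & info$bonds$a2 %in% uc, ,
                            drop = FALSE]
    g <- igraph::graph_from_data_frame(
      d = data.frame(from = as.character(sub_bonds$a1),
                     to = as.character(sub_bonds$a2)),
      directed = FALSE,
      vertices = data.frame(name = as.character(uc)))
    comp <- igraph::components(g)
    for (cid in seq_len(comp$no)) {
      atoms <- as.integer(names(comp$membership)[comp$membership == cid])
      if (length(atoms) >= 3) {
        b <- numeric(6)
        names(b) <- PHARM_CLASSES
        b["hydrophobic"] <- 1
        add_node(sort(atoms), b, FALSE)
      } else {
        for (a in atoms) add_node(a, setNames(numeric(6), PHARM_CLASSES),
                                  FALSE)
      }
    }
  }
  other <- setdiff(untyped, uc)
  for (a in other) add_node(a, setNames(numeric(6), PHARM_CLASSES), FALSE)

  if (length(atom_map) == 0) {  # unreachable fallback: one node, all atoms
    add_node(seq_len(n), setNames(numeric(6), PHARM_CLASSES), FALSE)
  }
  fmat <- do.call(rbind, feats)
  colnames(fmat) <- vocab$node_features
  ord <- order_nodes(atom_map)
  ri <- reindex_graph(atom_map, fmat, ord)
  edges <- group_edges(ri$atom_map, info$bonds, n)
  new_molecular_graph("P", info$smiles, n, ri$features, edges, NULL,
                      ri$atom_map, vocab$node_features)
}

split_pharm_matches <- function(raw_matches, definitions) {
  idx <- 0
  out <- list()
  for (cls in names(definitions)) {
    k <- length(definitions[[cls]])
    ms <- list()
    for (j in seq_len(k)) ms <- c(ms, raw_matches[[idx + j]])
    out[[cls]] <- ms
    idx <- idx + k
  }
  out
}

# --- JunctionTree graph -----------------------------------------------------

#' Build the junction-tree reduced graph
#'
#' Clusters are the smallest set of smallest rings, the non-ring bonds
#' (atom pairs), and junction atoms shared by three or more clusters.
#' Cluster-cluster links are resolved to a maximum spanning tree per
#' connected component, so the result is always a tree or forest.
#'
#' @param x SMILES string or `mol_info`.
#' @return a `molecular_graph` with representation "J" (always acyclic).
#' @export
build_junctiontree_graph <- function(x) {
  info <- as_mol_info(x)
  vocab <- feature_vocabulary("J")
  at <- info$atoms
  clusters <- info$rings
  types <- rep("ring", length(clusters))
  nb <- info$bonds[!info$bonds$in_ring, , drop = FALSE]
  if (nrow(nb) > 0) {
    clusters <- c(clusters, lapply(seq_len(nrow(nb)),
                                   function(b) c(nb$a1[b], nb$a2[b])))
    types <- c(types, rep("bond", nrow(nb)))
  }
  membership <- integer(info$n_atoms)
  for (cl in clusters) membership[cl] <- membership[cl] + 1L
  junction <- which(membership >= 3L)
  if (length(junction) > 0) {
    clusters <- c(clusters, as.list(junction))
    types <- c(types, rep("junction", length(junction)))
  }
  n_cl <- length(clusters)
  edges <- matrix(integer(0), ncol = 2)
  if (n_cl > 1) {
    cand <- list()
    is_junction <- types == "junction"
    for (i in seq_len(n_cl - 1)) {
      for (j in (i + 1):n_cl) {
        shared <- length(intersect(clusters[[i]], clusters[[j]]))
        if (shared > 0) {
          # junction-atom links take precedence in the spanning tree
          w <- shared + if (is_junction[i] || is_junction[j]) 100 else 0
          cand[[length(cand) + 1]] <- c(i, j, w)
        }
      }
    }
    if (length(cand) > 0) {
      cm <- do.call(rbind, cand)
      g <- igraph::graph_from_data_frame(
        d = data.frame(from = cm[, 1], to = cm[, 2], weight = -cm[, 3]),
        directed = FALSE,
        vertices = data.frame(name = seq_len(n_cl)))
      tree <- igraph::mst(g)
      el <- igraph::as_edgelist(tree)
      if (nrow(el) > 0) {
        edges <- cbind(as.integer(el[, 1]), as.integer(el[, 2]))
        edges <- cbind(pmin(edges[, 1], edges[, 2]),
                       pmax(edges[, 1], edges[, 2]))
      }
    }
  }
  feats <- t(vapply(seq_len(n_cl), function(k) {
    c(one_hot(types[k], c("ring", "bond", "junction")),
      length(clusters[[k]]),
      as.numeric(any(at$aromatic[clusters[[k]]])))
  }, numeric(vocab$node_width)))
  colnames(feats) <- vocab$node_features
  ord <- order_nodes(clusters)
  ri <- reindex_graph(clusters, feats, ord)
  edges <- if (nrow(edges) > 0) {
    e <- cbind(ri$perm[edges[, 1]], ri$perm[edges[, 2]])
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e[order(e[, 1], e[, 2]), , drop = FALSE]
  } else {
    edges
  }
  new_molecular_graph("J", info$smiles, info$n_atoms, ri$features, edges,
                      NULL, ri$atom_map, vocab$node_features)
}

# --- FunctionalGroup graph --------------------------------------------------

#' Build the functional-group reduced graph
#'
#' Greedy non-overlapping matching of a predefined SMARTS vocabulary
#' (largest patterns first, ties by vocabulary order), then rings, then
#' remaining bonds as atom-pair nodes; leftover isolated atoms become
#' singleton nodes, so every heavy atom is covered by at least one node.
#'
#' @param x SMILES string or `mol_info`.
#' @param vocab functional-group vocabulary data.frame
#'   (see [functional_group_vocabulary()]).
#' @param matches optional precomputed per-pattern atom matches (internal).
#' @return a `molecular_graph` with representation "F".
#' @export
build_functionalgroup_graph <- function(x,
                                        vocab = functional_group_vocabulary(),
                                        matches = NULL) {
  info <- as_mol_info(x)
  fvocab <- feature_vocabulary("F", fg_vocab = vocab)
  if (is.null(matches)) {
    matches <- match_smarts(info$smiles, vocab$smarts)[[1]]
  }
  n <- info$n_atoms
  at <- info$atoms
  covered <- logical(n)
  atom_map <- list()
  kinds <- character(0)     # vocabulary name, or "ring"/"pair"/"atom"

  cand <- list()
  for (g in seq_along(matches)) {
    for (m in matches[[g]]) {
      cand[[length(cand) + 1]] <- list(group = g, atoms = m)
    }
  }
  if (length(cand) > 0) {
    sizes <- vapply(cand, function(c) length(c$atoms), numeric(1))
    gidx <- vapply(cand, function(c) c$group, numeric(1))
    for (k in order(-sizes, gidx)) {
      a <- cand[[k]]$atoms
      if (!any(covered[a])) {
        covered[a] <- TRUE
        atom_map[[length(atom_map) + 1]] <- a
        kinds <- c(kinds, vocab$name[cand[[k]]$group])
      }
    }
  }
  for (ring in info$rings) {
    if (any(!covered[ring])) {
      covered[ring] <- TRUE
      atom_map[[length(atom_map) + 1]] <- ring
      kinds <- c(kinds, "ring")
    }
  }
  bd <- info$bonds
  for (pass in 1:2) {
    if (nrow(bd) == 0) break
    for (b in seq_len(nrow(bd))) {
      a1 <- bd$a1[b]; a2 <- bd$a2[b]
      take <- if (pass == 1) !covered[a1] && !covered[a2]
              else xor(covered[a1], covered[a2])
      if (take) {
        covered[c(a1, a2)] <- TRUE
        atom_map[[length(atom_map) + 1]] <- c(a1, a2)
        kinds <- c(kinds, "pair")
      }
    }
  }
  for (a in which(!covered)) {
    atom_map[[length(atom_map) + 1]] <- a
    kinds <- c(kinds, "atom")
  }

  classes <- c(vocab$name, "ring", "pair", "atom")
  feats <- t(vapply(seq_along(atom_map), function(k) {
    a <- atom_map[[k]]
    c(one_hot(kinds[k], classes),
      length(a),
      sum(at$element[a] != "C"),
      mean(at$aromatic[a]))
  }, numeric(fvocab$node_width)))
  colnames(feats) <- fvocab$node_features
  ord <- order_nodes(atom_map)
  ri <- reindex_graph(atom_map, feats, ord)
  edges <- group_edges(ri$atom_map, info$bonds, n)
  new_molecular_graph("F", info$smiles, n, ri$features, edges, NULL,
                      ri$atom_map, fvocab$node_features)
}

# --- batched building and statistics ---------------------------------------

#' Build graph representations for many molecules at once
#'
#' Batches all backend calls (parsing and SMARTS matching), which is much
#' faster than building per molecule.
#'
#' @param smiles character vector of SMILES.
#' @param representations subset of c("A","P","J","F").
#' @param fg_vocab functional-group vocabulary.
#' @param pharm_defs pharmacophore definitions.
#' @return list (one element per molecule) of named lists of
#'   `molecular_graph` objects; unparseable molecules give `NULL`.
#' @export
build_graphs <- function(smiles, representations = c("A", "P", "J", "F"),
                         fg_vocab = functional_group_vocabulary(),
                         pharm_defs = pharmacophore_definitions()) {
  representations <- match.arg(representations, c("A", "P", "J", "F"),
                               several.ok = TRUE)
  infos <- parse_molecules(smiles)
  ok <- !vapply(infos, is.null, logical(1))
  canon <- vapply(infos[ok], `[[`, character(1), "smiles")
  pmatch_all <- NULL
  fmatch_all <- NULL
  if ("P" %in% representations && length(canon) > 0) {
    all_sm <- unlist(pharm_defs, use.names = FALSE)
    pmatch_all <- match_smarts(canon, all_sm)
  }
  if ("F" %in% representations && length(canon) > 0) {
    fmatch_all <- match_smarts(canon, fg_vocab$smarts)
  }
  out <- vector("list", length(smiles))
  j <- 0
  for (i in seq_along(smiles)) {
    if (!ok[i]) next
    j <- j + 1
    info <- infos[[i]]
    gl <- list()
    for (r in representations) {
      gl[[r]] <- switch(r,
        A = build_atom_graph(info),
        P = build_pharmacophore_graph(
          info, definitions = pharm_defs,
          matches = split_pharm_matches(pmatch_all[[j]], pharm_defs)),
        J = build_junctiontree_graph(info),
        F = build_functionalgroup_graph(info, vocab = fg_vocab,
                                        matches = fmatch_all[[j]])
      )
    }
    out[[i]] <- gl
  }
  out
}

#' Node-count statistics of graph reductions
#'
#' Quantifies how strongly each representation coarsens the atom graph
#' over a set of molecules.
#'
#' @param smiles character vector of SMILES (or a dataset data.frame with a
#'   `smiles` column).
#' @param representations representations to compare.
#' @return data.frame with per-representation mean and median node counts.
#' @export
reduction_statistics <- function(smiles,
                                 representations = c("A", "P", "J", "F")) {
  if (is.data.frame(smiles)) smiles <- smiles$smiles
  graphs <- build_graphs(smiles, representations)
  graphs <- graphs[!vapply(graphs, is.null, logical(1))]
  if (length(graphs) == 0) stop("no valid molecules", call. = FALSE)
  counts <- sapply(representations, function(r)
    vapply(graphs, function(g) nrow(g[[r]]$node_features), numeric(1)))
  counts <- matrix(counts, nrow = length(graphs),
                   dimnames = list(NULL, representations))
  data.frame(
    representation = representations,
    mean_nodes = colMeans(counts),
    median_nodes = apply(counts, 2, median),
    row.names = NULL
  )
}
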