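# Potential-substructures view: fragment generation, importance
# detection, per-fragment statistics, the fragment importance score, and
# the three-condition selection with redundancy removal.

#' Extraction configuration for the potential-substructures view
#'
#' @param p_f percentile of the molecule's atom attention a fragment's
#'   median attention must exceed to count as important (default 75).
#' @param p_s percentile, among all fragments, of the important-compound
#'   support count a fragment must reach (default 70).
#' @param min_important_pct minimum important-fragment percentage (fixed
#'   default 50).
#' @param fragmenters subset of c("BRICS", "RECAP", "GRINDER").
#' @param min_atoms,max_atoms fragment size window (default 3-20 atoms).
#' @return an `extraction_config` list.
#' @export
extraction_config <- function(p_f = 75, p_s = 70, min_important_pct = 50,
                              fragmenters = c("BRICS", "RECAP", "GRINDER"),
                              min_atoms = 3, max_atoms = 20) {
  fragmenters <- match.arg(fragmenters,
                           c("BRICS", "RECAP", "GRINDER"),
                           several.ok = TRUE)
  stopifnot(p_f > 0, p_f < 100, p_s > 0, p_s < 100,
            min_atoms >= 1, max_atoms >= min_atoms)
  structure(list(p_f = p_f, p_s = p_s,
                 min_important_pct = min_important_pct,
                 fragmenters = fragmenters,
                 min_atoms = min_atoms, max_atoms = max_atoms),
            class = "extraction_config")
}

#' RECAP bond-cleavage rules
#' @param path optional YAML override of the shipped rules.
#' @return data.frame with `name`, `smarts` and cut positions.
#' @export
recap_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "recap_rules.yaml", package = "redgraph")
  }
  raw <- yaml::read_yaml(path)$rules
  data.frame(
    name = vapply(raw, `[[`, character(1), "name"),
    smarts = vapply(raw, `[[`, character(1), "smarts"),
    cut1 = vapply(raw, function(r) as.integer(r$cut[[1]]), integer(1)),
    cut2 = vapply(raw, function(r) as.integer(r$cut[[2]]), integer(1)),
    stringsAsFactors = FALSE
  )
}

bond_index_of <- function(info, a, b) {
  which((info$bonds$a1 == pmin(a, b) & info$bonds$a2 == pmax(a, b)) |
          (info$bonds$a1 == pmax(a, b) & info$bonds$a2 == pmin(a, b)))
}

# connected components of the molecule after removing the given bonds
components_after_cuts <- function(info, cut_bonds) {
  keep <- setdiff(seq_len(nrow(info$bonds)), cut_bonds)
  parent <- seq_len(info$n_atoms)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (b in keep) {
    ra <- find(info$bonds$a1[b]); rb <- find(info$bonds$a2[b])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(info$n_atoms), find, integer(1))
  unname(split(seq_len(info$n_atoms), roots))
}

#' Generate candidate fragments of a molecule
#'
#' Fragments come from BRICS bonds (all cleaved at once), RECAP rule
#' bonds (all cleaved at once), and exhaustive single and double cuts of
#' acyclic bonds ("GRINDER"). Only acyclic bonds are ever cut, so no ring
#' is broken; pieces outside the size window are dropped, and fragments
#' are deduplicated by atom set.
#'
#' @param x SMILES string or `mol_info`.
#' @param config an [extraction_config()].
#' @return data.frame with `smiles` (canonical fragment SMILES) and a
#'   list-column `atoms` of atom-index sets.
#' @export
fragment_molecule <- function(x, config = extraction_config()) {
  info <- as_mol_info(x)
  acyclic <- which(!info$bonds$in_ring)
  scenarios <- list()
  if ("GRINDER" %in% config$fragmenters) {
    for (b in acyclic) scenarios[[length(scenarios) + 1]] <- b
    if (length(acyclic) >= 2) {
      cmb <- utils::combn(acyclic, 2)
      for (k in seq_len(ncol(cmb))) {
        scenarios[[length(scenarios) + 1]] <- cmb[, k]
      }
    }
  }
  if ("BRICS" %in% config$fragmenters) {
    bb <- brics_bonds(info$smiles)[[1]]
    if (nrow(bb) > 0) {
      idx <- unlist(lapply(seq_len(nrow(bb)), function(k)
        bond_index_of(info, bb[k, 1], bb[k, 2])))
      idx <- intersect(idx, acyclic)
      if (length(idx) > 0) scenarios[[length(scenarios) + 1]] <- idx
    }
  }
  if ("RECAP" %in% config$fragmenters) {
    rules <- recap_rules()
    ms <- match_smarts(info$smiles, rules$smarts)[[1]]
    idx <- integer(0)
    for (r in seq_len(nrow(rules))) {
      for (m in ms[[r]]) {
        idx <- c(idx, bond_index_of(info, m[rules$cut1[r]],
                                    m[rules$cut2[r]]))
      }
    }
    idx <- intersect(unique(idx), acyclic)
    if (length(idx) > 0) scenarios[[length(scenarios) + 1]] <- idx
  }
  # whole single-fragment molecule counts when it fits the window
  pieces <- components_after_cuts(info, integer(0))
  for (sc in scenarios) {
    pieces <- c(pieces, components_after_cuts(info, sc))
  }
  sizes <- vapply(pieces, length, integer(1))
  pieces <- pieces[sizes >= config$min_atoms & sizes <= config$max_atoms]
  if (length(pieces) == 0) {
    return(data.frame(smiles = character(0),
                      atoms = I(list()), stringsAsFactors = FALSE))
  }
  keys <- vapply(pieces, function(a) paste(a, collapse = ","), character(1))
  pieces <- pieces[!duplicated(keys)]
  smi <- fragment_smiles(rep(info$smiles, length(pieces)), pieces)
  ok <- !is.na(smi)
  data.frame(smiles = smi[ok], atoms = I(pieces[ok]),
             stringsAsFactors = FALSE)
}

#' Flag important fragments of one molecule
#'
#' A fragment is important when the median of its atoms' attention
#' strictly exceeds the `p_f` percentile (linear interpolation) of the
#' whole molecule's atom attention.
#'
#' @param attention atom-level combined attention vector.
#' @param fragments data.frame from [fragment_molecule()] (or a list of
#'   atom-index sets).
#' @param p_f importance percentile.
#' @return logical vector, one flag per fragment.
#' @export
detect_important_fragments <- function(attention, fragments, p_f = 75) {
  atom_sets <- if (is.data.frame(fragments)) fragments$atoms else fragments
  thr <- stats::quantile(attention, p_f / 100, type = 7, names = FALSE)
  vapply(atom_sets, function(a) {
    stats::median(attention[a]) > thr
  }, logical(1))
}

#' Fragment importance score
#'
#' The mean, over a fragment's occurrences, of the difference between the
#' fragment's average attention and its molecule's average attention.
#'
#' @param occurrences data.frame with columns `m_frag` and `m_mol` (one
#'   row per occurrence).
#' @return scalar score.
#' @export
score_fragment <- function(occurrences) {
  if (nrow(occurrences) == 0) stop("no occurrences", call. = FALSE)
  mean(occurrences$m_frag - occurrences$m_mol)
}

#' Per-fragment statistics over a molecule set
#'
#' Fragments every molecule, flags important occurrences, and aggregates
#' by canonical fragment SMILES: the number of compounds containing the
#' fragment, the number where it is important, the important percentage,
#' and the fragment importance score.
#'
#' @param attention named list (by molecule id) of atom-level combined
#'   attention vectors.
#' @param smiles named character vector of the same molecules' canonical
#'   SMILES.
#' @param config an [extraction_config()].
#' @return a `fragment_statistics` list with `stats` (per-fragment
#'   data.frame) and `occurrences` (per-occurrence data.frame).
#' @export
fragment_statistics <- function(attention, smiles,
                                config = extraction_config()) {
  ids <- names(attention)
  stopifnot(!is.null(ids), all(ids %in% names(smiles)))
  # prefetch backend results for the whole set in two batched calls
  uniq <- unique(unname(smiles[ids]))
  if ("BRICS" %in% config$fragmenters) invisible(brics_bonds(uniq))
  if ("RECAP" %in% config$fragmenters) {
    invisible(match_smarts(uniq, recap_rules()$smarts))
  }
  occ <- list()
  for (id in sort(ids)) {
    att <- attention[[id]]
    frags <- fragment_molecule(smiles[[id]], config)
    if (nrow(frags) == 0) next
    imp <- detect_important_fragments(att, frags, config$p_f)
    occ[[id]] <- data.frame(
      fragment = frags$smiles,
      molecule = id,
      m_frag = vapply(frags$atoms, function(a) mean(att[a]), numeric(1)),
      m_mol = mean(att),
      important = imp,
      atoms = I(frags$atoms),
      stringsAsFactors = FALSE)
  }
  occurrences <- if (length(occ) > 0) do.call(rbind, occ) else
    data.frame(fragment = character(0), molecule = character(0),
               m_frag = numeric(0), m_mol = numeric(0),
               important = logical(0), atoms = I(list()))
  rownames(occurrences) <- NULL
  by_frag <- split(seq_len(nrow(occurrences)), occurrences$fragment)
  stats <- do.call(rbind, lapply(names(by_frag), function(f) {
    rows <- occurrences[by_frag[[f]], ]
    n_comp <- length(unique(rows$molecule))
    n_imp <- length(unique(rows$molecule[rows$important]))
    data.frame(fragment = f,
               n_compounds = n_comp,
               n_important = n_imp,
               important_pct = 100 * n_imp / n_comp,
               score = score_fragment(rows),
               n_occurrences = nrow(rows),
               stringsAsFactors = FALSE)
  }))
  if (is.null(stats)) {
    stats <- data.frame(fragment = character(0), n_compounds = integer(0),
                        n_important = integer(0), important_pct = numeric(0),
                        score = numeric(0), n_occurrences = integer(0))
  }
  rownames(stats) <- NULL
  structure(list(stats = stats, occurrences = occurrences,
                 config = config),
            class = "fragment_statistics")
}

frag_contained_in <- function(occurrences, f, g) {
  # f is a (strict) subgraph of g if, in some molecule, one of f's
  # occurrence atom sets is a proper subset of one of g's
  of <- occurrences[occurrences$fragment == f, ]
  og <- occurrences[occurrences$fragment == g, ]
  for (mol in intersect(of$molecule, og$molecule)) {
    fa <- of$atoms[of$molecule == mol]
    ga <- og$atoms[og$molecule == mol]
    for (a in fa) for (b in ga) {
      if (length(a) < length(b) && all(a %in% b)) return(TRUE)
    }
  }
  FALSE
}

#' Select potential substructures
#'
#' Keeps fragments meeting all three conditions: important percentage at
#' least `min_important_pct`; important-compound support at or above the
#' `p_s` percentile of support counts among all fragments; score strictly
#' positive. A kept fragment that is a subgraph of another kept fragment
#' with an equal-or-higher score is then dropped as redundant.
#'
#' @param fs a `fragment_statistics` object.
#' @param config an [extraction_config()] (defaults to the one stored in
#'   `fs`).
#' @return data.frame of selected fragments, ranked by score.
#' @export
select_potential_substructures <- function(fs, config = NULL) {
  stopifnot(inherits(fs, "fragment_statistics"))
  config <- config %||% fs$config
  st <- fs$stats
  if (nrow(st) == 0) {
    warning("no fragments available", call. = FALSE)
    return(st)
  }
  support_cut <- stats::quantile(st$n_important, config$p_s / 100,
                                 type = 7, names = FALSE)
  keep <- st$important_pct >= config$min_important_pct &
    st$n_important >= support_cut &
    st$score > 0
  sel <- st[keep, , drop = FALSE]
  if (nrow(sel) == 0) {
    warning("no fragment passes all selection conditions", call. = FALSE)
    return(sel)
  }
  sel <- sel[order(-sel$score, sel$fragment), , drop = FALSE]
  redundant <- logical(nrow(sel))
  for (i in seq_len(nrow(sel))) {
    for (j in seq_len(nrow(sel))) {
      if (i == j || redundant[j]) next
      if (sel$score[i] <= sel$score[j] &&
          frag_contained_in(fs$occurrences, sel$fragment[i],
                            sel$fragment[j])) {
        redundant[i] <- TRUE
        break
      }
    }
  }
  out <- sel[!redundant, , drop = FALSE]
  rownames(out) <- NULL
  out
}
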