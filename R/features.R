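# Node/edge feature vocabularies for the four graph representations.
# Slot order is part of the package contract: trained models store the
# vocabulary they were built with.

ELEMENTS <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P", "other")
HYBRIDIZATIONS <- c("SP", "SP2", "SP3", "other")
PHARM_CLASSES <- c("donor", "acceptor", "positive", "negative",
                   "hydrophobic", "aromatic")

#' Load the pharmacophore SMARTS definitions
#'
#' @param path optional YAML file overriding the shipped definitions.
#' @return named list of SMARTS character vectors (donor, acceptor,
#'   positive, negative).
#' @export
pharmacophore_definitions <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pharmacophore_features.yaml",
                        package = "redgraph")
  }
  defs <- yaml::read_yaml(path)
  lapply(defs, function(x) as.character(unlist(x)))
}

#' Load the functional-group SMARTS vocabulary
#'
#' @param path optional YAML file overriding the shipped vocabulary.
#' @return data.frame with columns `name` and `smarts`, in matching
#'   priority order (descending pattern size applied at match time).
#' @export
functional_group_vocabulary <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "functional_groups.yaml",
                        package = "redgraph")
  }
  raw <- yaml::read_yaml(path)$groups
  data.frame(
    name = vapply(raw, `[[`, character(1), "name"),
    smarts = vapply(raw, `[[`, character(1), "smarts"),
    stringsAsFactors = FALSE
  )
}

#' Feature vocabulary of a graph representation
#'
#' Returns the ordered node (and, for the atom graph, edge) feature names;
#' the node width defines the input dimensionality of the network encoder.
#'
#' @param representation one of "A", "P", "J", "F".
#' @param fg_vocab functional-group vocabulary (data.frame), used for "F".
#' @return list with `node_features`, `edge_features` (possibly NULL) and
#'   their widths.
#' @export
feature_vocabulary <- function(representation,
                               fg_vocab = functional_group_vocabulary()) {
  representation <- match.arg(representation, c("A", "P", "J", "F"))
  node <- switch(representation,
    A = c(paste0("element_", ELEMENTS),
          paste0("degree_", 0:5),
          "formal_charge", "aromatic",
          paste0("hybridization_", HYBRIDIZATIONS),
          paste0("num_h_", 0:4),
          "in_ring"),
    P = c(PHARM_CLASSES, "in_ring", "size"),
    J = c("cluster_ring", "cluster_bond", "cluster_junction",
          "size", "aromatic"),
    F = c(paste0("group_", fg_vocab$name),
          "group_ring", "group_pair", "group_atom",
          "size", "n_hetero", "aromatic_fraction")
  )
  edge <- if (representation == "A") {
    c("bond_single", "bond_double", "bond_triple", "bond_aromatic",
      "conjugated", "in_ring")
  } else {
    NULL
  }
  stopifnot(!anyDuplicated(node))
  list(node_features = node, node_width = length(node),
       edge_features = edge, edge_width = length(edge))
}

one_hot <- function(value, levels) {
  v <- numeric(length(levels))
  i <- match(value, levels)
  if (is.na(i)) i <- length(levels)  # trailing slot doubles as "other"
  v[i] <- 1
  v
}
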