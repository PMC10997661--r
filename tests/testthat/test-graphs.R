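test_that("atom graph mirrors atoms and bonds with perceived chemistry", {
  asp <- build_atom_graph("CC(=O)OC1=CC=CC=C1C(=O)O")
  expect_equal(nrow(asp$node_features), 13)
  expect_equal(nrow(asp$edges), 13)
  expect_equal(asp$atom_map, as.list(1:13))

  eth <- build_atom_graph("CC")
  expect_equal(nrow(eth$node_features), 2)
  expect_equal(nrow(eth$edges), 1)

  bz <- build_atom_graph("c1ccccc1")
  expect_true(all(bz$node_features[, "aromatic"] == 1))
  expect_true(all(bz$edge_features[, "bond_aromatic"] == 1))
})

test_that("pharmacophore graph collapses rings and types hetero atoms", {
  bz <- build_pharmacophore_graph("c1ccccc1")
  expect_equal(nrow(bz$node_features), 1)
  expect_equal(bz$node_features[1, "aromatic"], c(aromatic = 1))
  expect_equal(bz$atom_map[[1]], 1:6)

  etoh <- build_pharmacophore_graph("CCO")
  feats <- etoh$node_features
  o_row <- which(feats[, "donor"] == 1 & feats[, "acceptor"] == 1)
  expect_length(o_row, 1)
  # node feature width: six pharmacophore bits plus declared auxiliaries
  expect_equal(ncol(feats), length(feature_vocabulary("P")$node_features))
  expect_equal(colnames(feats)[1:6],
               c("donor", "acceptor", "positive", "negative",
                 "hydrophobic", "aromatic"))
})

test_that("hydrophobic chains collapse and linkers keep topology", {
  g <- build_pharmacophore_graph("CCCCCCO")  # hexyl chain + hydroxyl
  hydro <- which(g$node_features[, "hydrophobic"] == 1)
  expect_length(hydro, 1)
  expect_gte(length(g$atom_map[[hydro]]), 3)
  # graph stays connected like the molecule
  expect_true(igraph::is_connected(igraph::graph_from_edgelist(
    g$edges, directed = FALSE)))
})

test_that("junction tree handles rings, chains and stays acyclic", {
  ch <- build_junctiontree_graph("C1CCCCC1")
  expect_equal(nrow(ch$node_features), 1)
  expect_equal(nrow(ch$edges), 0)

  bu <- build_junctiontree_graph("CCCC")
  expect_equal(nrow(bu$node_features), 3)
  expect_equal(nrow(bu$edges), 2)  # a path: 3 bond nodes, acyclic

  asp <- build_junctiontree_graph("CC(=O)OC1=CC=CC=C1C(=O)O")
  expect_equal(nrow(asp$edges), nrow(asp$node_features) - 1)
})

test_that("functional group graph matches vocabulary then covers the rest", {
  ac <- build_functionalgroup_graph("CC(=O)O")
  kinds <- apply(ac$node_features[, grepl("^group_", colnames(ac$node_features))],
                 1, function(r) sub("^group_", "",
                                    colnames(ac$node_features)[which(r == 1)]))
  expect_true("carboxylic_acid" %in% kinds)
  covered <- sort(unique(unlist(ac$atom_map)))
  expect_equal(covered, 1:4)

  bz <- build_functionalgroup_graph("c1ccccc1")
  expect_equal(nrow(bz$node_features), 1)
})

test_that("coverage, acyclicity and determinism hold on generated molecules", {
  pool <- generated_pool(50)
  graphs <- build_graphs(pool$smiles, c("A", "P", "J", "F"))
  for (gl in graphs) {
    n <- gl$A$n_atoms
    # A: exactly one node per atom; J, F: total coverage
    expect_equal(sort(unlist(gl$A$atom_map)), seq_len(n))
    expect_equal(sort(unique(unlist(gl$J$atom_map))), seq_len(n))
    expect_equal(sort(unique(unlist(gl$F$atom_map))), seq_len(n))
    # J is a forest: no cycles
    if (nrow(gl$J$edges) > 0) {
      jg <- igraph::graph_from_edgelist(gl$J$edges, directed = FALSE)
      expect_equal(igraph::girth(jg)$girth, Inf)
    }
    # P never splits components
    comp_count <- function(edges, nv) {
      g <- igraph::make_empty_graph(nv, directed = FALSE)
      if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
      igraph::components(g)$no
    }
    expect_lte(comp_count(gl$P$edges, nrow(gl$P$node_features)),
               comp_count(gl$A$edges, nrow(gl$A$node_features)))
  }
  # determinism: same SMILES, same graphs
  again <- build_graphs(pool$smiles[1:5], c("A", "P", "J", "F"))
  expect_identical(graphs[1:5], again)
})

test_that("reduction statistics reproduce per-molecule recounts and ordering", {
  pool <- generated_pool(40)
  stats <- reduction_statistics(pool$smiles)
  graphs <- build_graphs(pool$smiles, c("A", "P", "J", "F"))
  manual <- vapply(c("A", "P", "J", "F"), function(r)
    mean(vapply(graphs, function(g) nrow(g[[r]]$node_features),
                numeric(1))), numeric(1))
  expect_equal(stats$mean_nodes, unname(manual[stats$representation]))
  ord <- setNames(stats$mean_nodes, stats$representation)
  expect_lte(ord[["F"]], ord[["J"]])
  expect_lte(ord[["P"]], ord[["A"]])
})
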