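test_that("min-max normalization follows the formula and degenerate rule", {
  expect_equal(minmax_normalize(c(0.2, 0.4, 0.6)), c(0, 0.5, 1))
  expect_equal(minmax_normalize(c(3, 3, 3)), c(0.5, 0.5, 0.5))
  v <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(v), v)  # idempotent on [0,1]-spanning input
  expect_error(minmax_normalize(numeric(0)), "empty")
})

test_that("atom mapping sums overlapping nodes then renormalizes", {
  # two nodes {1,2} w=0.6 and {2,3} w=0.4: atoms get (0.6, 1.0, 0.4)
  g <- fake_graph(list(c(1, 2), c(2, 3)), 3)
  expect_equal(map_to_atoms(g, c(0.6, 0.4)), c(1 / 3, 1, 0))
  # atom graph: identity mapping then normalization
  ga <- fake_graph(list(1, 2, 3), 3, representation = "A")
  expect_equal(map_to_atoms(ga, c(0.1, 0.2, 0.3)), c(0, 0.5, 1))
  # a single node covering everything: uniform, hence neutral 0.5
  gu <- fake_graph(list(1:4), 4)
  expect_equal(map_to_atoms(gu, 0.8), rep(0.5, 4))
  # uncovered atoms receive zero before normalization
  gpart <- fake_graph(list(c(1, 2)), 3)
  expect_equal(map_to_atoms(gpart, 1), c(1, 1, 0))
  expect_error(map_to_atoms(g, c(1, 2, 3)))
})

test_that("max-combination is elementwise, idempotent and monotone", {
  expect_equal(combine_graphs(list(c(0.2, 0.9), c(0.7, 0.1))), c(0.7, 0.9))
  x <- c(0.3, 0.6, 0.1)
  expect_equal(combine_graphs(list(x)), x)
  expect_equal(combine_graphs(list(x, x)), x)
  expect_error(combine_graphs(list(c(1, 2), c(1, 2, 3))), "length")
  # monotone: raising any input never lowers any output
  set.seed(41)
  for (i in 1:20) {
    a <- runif(5); b <- runif(5)
    base <- combine_graphs(list(a, b))
    a2 <- a
    j <- sample(5, 1)
    a2[j] <- a2[j] + runif(1)
    expect_true(all(combine_graphs(list(a2, b)) >= base))
  }
})

test_that("the raw-to-combined pipeline is invariant to atom reindexing", {
  set.seed(17)
  n_atoms <- 6
  maps1 <- list(c(1, 2), c(2, 3, 4), c(5), c(5, 6))
  maps2 <- list(c(1, 2, 3), c(4, 5), c(6))
  w1 <- runif(4); w2 <- runif(3)
  pipeline <- function(m1, m2, na) {
    combine_graphs(list(map_to_atoms(fake_graph(m1, na), w1),
                        map_to_atoms(fake_graph(m2, na), w2)))
  }
  out <- pipeline(maps1, maps2, n_atoms)
  perm <- sample(n_atoms)  # perm[old] = new index
  out_perm <- pipeline(lapply(maps1, function(a) perm[a]),
                       lapply(maps2, function(a) perm[a]), n_atoms)
  expect_equal(out_perm[perm], out, tolerance = 1e-12)
})

test_that("attention_result runs the documented extraction order", {
  tt <- tiny_trained()
  model <- tt$fold$model
  res <- attention_result(model, tt$graphs[[1]])
  n_atoms <- tt$graphs[[1]]$A$n_atoms
  expect_length(res$combined, n_atoms)
  expect_true(all(res$combined >= 0 & res$combined <= 1))
  for (r in model$scheme) {
    expect_equal(res$node_attention[[r]],
                 minmax_normalize(res$raw_attention[[r]]))
    expect_equal(res$atom_attention[[r]],
                 map_to_atoms(tt$graphs[[1]][[r]], res$node_attention[[r]]))
  }
  expect_equal(res$combined, do.call(pmax, res$atom_attention))
})

test_that("single prediction view writes the numeric vector verbatim", {
  tt <- tiny_trained()
  res <- attention_result(tt$fold$model, tt$graphs[[2]])
  prefix <- tempfile()
  files <- single_prediction_view(tt$gen$records$smiles[2], res$combined,
                                  prefix)
  dump <- jsonlite::read_json(paste0(prefix, ".json"),
                              simplifyVector = TRUE)
  expect_equal(dump$attention, res$combined, tolerance = 1e-12)
  svg <- paste0(prefix, ".svg")
  expect_true(file.exists(svg))
  expect_match(readLines(svg, n = 1, warn = FALSE), "xml|svg")
})

test_that("fold averaging takes the mean of per-fold combined vectors", {
  tt <- tiny_trained()
  models <- list(tt$fold$model, tt$fold$model)
  fa <- fold_attention(models, tt$graphs[[1]])
  single <- attention_result(tt$fold$model, tt$graphs[[1]])$combined
  expect_equal(fa$combined, single)  # identical folds: mean is the vector
  expect_equal(dim(fa$per_fold), c(2, length(single)))
})

test_that("node features view matches a direct two-pass recomputation", {
  tt <- tiny_trained()
  models <- list(tt$fold$model)
  graphs <- tt$graphs[1:10]
  nfs <- node_features_view(models, graphs)
  expect_s3_class(nfs, "node_feature_summary")
  expect_true(all(nfs$count >= 1))
  expect_true(all(nfs$mean_attention >= 0 & nfs$mean_attention <= 1))
  # oracle: recompute one feature's mean attention by brute force
  feat <- nfs$feature[which.max(nfs$count)]
  rep_of <- nfs$representation[which.max(nfs$count)]
  total <- 0; cnt <- 0
  for (g in graphs) {
    ro <- readout_molecule(models[[1]], g[[rep_of]])
    att <- minmax_normalize(ro$attention)
    fmat <- g[[rep_of]]$node_features
    for (k in seq_len(nrow(fmat))) {
      if (feat %in% colnames(fmat)[fmat[k, ] == 1]) {
        total <- total + att[k]; cnt <- cnt + 1
      }
    }
  }
  row <- nfs[nfs$feature == feat & nfs$representation == rep_of, ]
  expect_equal(row$count, cnt)
  expect_equal(row$mean_attention, total / cnt, tolerance = 1e-12)
  # counts: multi-hot nodes contribute to several features
  n_nodes <- sum(vapply(graphs, function(g)
    nrow(g[[rep_of]]$node_features), integer(1)))
  expect_gte(sum(nfs$count[nfs$representation == rep_of]), n_nodes)
  # empty filter is an error
  expect_error(node_features_view(models, graphs,
                                  filter = function(p) p > 2), "filter")
})

test_that("attention correlation spans molecules and stays in [-1, 1]", {
  tt <- tiny_trained()
  ac <- attention_correlation(tt$fold$model, tt$graphs[1:15])
  ok <- ac$per_molecule$correlation[!is.na(ac$per_molecule$correlation)]
  expect_gt(length(ok), 0)
  expect_true(all(ok >= -1 - 1e-12 & ok <= 1 + 1e-12))
  expect_true(is.finite(ac$summary["mean"]))
})
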