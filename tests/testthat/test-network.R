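make_small_model <- function(scheme = c("A", "J"), d = 8, seed = 5,
                             smiles = c("CC(=O)OC1=CC=CC=C1C(=O)O",
                                        "C1CC1CCO", "CCCNC(=O)C")) {
  graphs <- build_graphs(smiles, unique(c(scheme, "A")))
  prep <- prepare_scheme_graphs(graphs, scheme)
  fw <- vapply(scheme, function(r)
    ncol(prep[[1]][[r]]$node_features), integer(1))
  names(fw) <- scheme
  cfg <- model_config(embedding_dim = d)
  list(model = new_model(scheme, fw, cfg, seed = seed), prep = prep,
       config = cfg)
}

test_that("encoding is a deterministic linear map of the declared width", {
  ms <- make_small_model(scheme = "A")
  g <- ms$prep[[1]]$A
  H <- encode_nodes(ms$model, g)
  expect_equal(dim(H), c(nrow(g$node_features), 8))
  expect_identical(H, encode_nodes(ms$model, g))
  # zero features give the bias row
  g0 <- g
  g0$node_features[] <- 0
  H0 <- encode_nodes(ms$model, g0)
  expect_equal(H0[1, ], ms$model$params$reps$A$benc,
               ignore_attr = TRUE)
  # width mismatch is a configuration error
  gbad <- g
  gbad$node_features <- g$node_features[, -1, drop = FALSE]
  expect_error(encode_nodes(ms$model, gbad), "width")
})

test_that("one message-passing round sums neighbour and edge messages", {
  # 3-node path a-b-c: the centre aggregate is self + both neighbours
  ms <- make_small_model(scheme = "A", smiles = c("CCO"))
  g <- ms$prep[[1]]$A
  p <- ms$model$params$reps$A
  H0 <- encode_nodes(ms$model, g)
  batch <- redgraph:::graph_batch(list(g))
  ET <- batch$SE %*% t(p$Wedge) + outer(batch$deg, p$bedge)
  centre <- which(batch$deg == 2)
  expected <- H0[centre, ] + colSums(H0[-centre, , drop = FALSE]) +
    ET[centre, ]
  out <- redgraph:::rep_forward(p, batch, steps = 1, readout_steps = 1,
                                slope = 0.2)
  expect_equal(out$cache$mp[[1]]$a[centre, ], expected)
})

test_that("node embeddings are permutation-equivariant", {
  ms <- make_small_model(scheme = "J")
  g <- ms$prep[[2]]$J
  n <- nrow(g$node_features)
  perm <- c(n, seq_len(n - 1))
  gp <- g
  gp$node_features <- g$node_features[perm, , drop = FALSE]
  gp$atom_map <- g$atom_map[perm]
  inv <- match(seq_len(n), perm)
  if (nrow(g$edges) > 0) gp$edges <- matrix(inv[g$edges], ncol = 2)
  H <- embed_nodes(ms$model, g)
  Hp <- embed_nodes(ms$model, gp)
  expect_equal(Hp, H[perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("readout attention is a distribution and respects symmetry", {
  ms <- make_small_model(scheme = c("A", "J"))
  for (i in seq_along(ms$prep)) {
    for (r in c("A", "J")) {
      ro <- readout_molecule(ms$model, ms$prep[[i]][[r]])
      expect_true(all(ro$attention >= 0))
      expect_equal(sum(ro$attention), 1, tolerance = 1e-6)
    }
  }
  # single node: softmax over one element
  g1 <- fake_graph(list(1:2), 2)
  g1$node_features <- matrix(runif(2), 1, 2,
                             dimnames = list(NULL, c("f1", "f2")))
  fw <- c(J = 2L)
  m1 <- new_model("J", fw, model_config(embedding_dim = 4), seed = 1)
  expect_equal(readout_molecule(m1, g1)$attention, 1)
  # two identical disconnected nodes: equal weight by symmetry
  g2 <- fake_graph(list(1, 2), 2)
  g2$node_features <- matrix(c(0.3, 0.7, 0.3, 0.7), 2, 2, byrow = TRUE,
                             dimnames = list(NULL, c("f1", "f2")))
  expect_equal(readout_molecule(m1, g2)$attention, c(0.5, 0.5),
               tolerance = 1e-12)
})

test_that("molecule embedding is invariant to node reordering", {
  ms <- make_small_model(scheme = "J")
  g <- ms$prep[[1]]$J
  n <- nrow(g$node_features)
  perm <- rev(seq_len(n))
  gp <- g
  gp$node_features <- g$node_features[perm, , drop = FALSE]
  gp$atom_map <- g$atom_map[perm]
  inv <- match(seq_len(n), perm)
  if (nrow(g$edges) > 0) gp$edges <- matrix(inv[g$edges], ncol = 2)
  e1 <- readout_molecule(ms$model, g)$embedding
  e2 <- readout_molecule(ms$model, gp)$embedding
  expect_equal(e1, e2, tolerance = 1e-5)
})

test_that("multi-graph forward concatenates embeddings before the head", {
  ms <- make_small_model(scheme = c("A", "J"), d = 8)
  out <- forward_model(ms$model, ms$prep[[1]])
  expect_named(out$embeddings, c("A", "J"))
  expect_length(out$embeddings$A, 8)
  expect_equal(ncol(ms$model$params$head$W1), 16)  # 2 x embedding_dim
  expect_gte(out$prediction, 0)
  expect_lte(out$prediction, 1)
})

test_that("analytic gradients match finite differences", {
  ms <- make_small_model(scheme = c("A", "J"), d = 5)
  batches <- lapply(setNames(c("A", "J"), c("A", "J")), function(r)
    redgraph:::graph_batch(lapply(ms$prep, `[[`, r)))
  y <- c(1, 0, 1)
  lg <- redgraph:::model_loss_grads(ms$model, batches, y)
  paths <- list(c("head", "W1"), c("head", "W2"),
                c("reps", "A", "Wenc"), c("reps", "A", "Wedge"),
                c("reps", "A", "gru_mp", "Un"), c("reps", "A", "att_a"),
                c("reps", "J", "Wp"), c("reps", "J", "gru_ro", "Wz"),
                c("reps", "J", "att_b"))
  getleaf <- function(p, path) { for (k in path) p <- p[[k]]; p }
  for (path in paths) {
    idx <- 2
    eps <- 1e-6
    for (sgn in c(1, -1)) {
      m2 <- ms$model
      leaf <- getleaf(m2$params, path)
      leaf[idx] <- leaf[idx] + sgn * eps
      expr <- paste0("m2$params", paste0("[['", path, "']]",
                                         collapse = ""))
      eval(parse(text = paste0(expr, " <- leaf")))
      l <- redgraph:::model_loss_grads(m2, batches, y)$loss
      if (sgn == 1) lplus <- l else lminus <- l
    }
    numeric_grad <- (lplus - lminus) / (2 * eps)
    analytic <- getleaf(lg$grads, path)[idx]
    expect_equal(analytic, numeric_grad, tolerance = 1e-5)
  }
})

test_that("training a fold is bitwise reproducible on CPU", {
  tt <- tiny_trained()
  fr2 <- train_fold(tt$gen$records, tt$graphs, "A+J", tt$split, 1,
                    tt$config)
  expect_identical(tt$fold$loss_history, fr2$loss_history)
  expect_identical(tt$fold$model$params, fr2$model$params)
  expect_identical(tt$fold$test_predictions$prediction,
                   fr2$test_predictions$prediction)
})

test_that("gradients reach every representation's encoder in a scheme", {
  ms <- make_small_model(scheme = c("A", "J"), d = 6)
  batches <- lapply(setNames(c("A", "J"), c("A", "J")), function(r)
    redgraph:::graph_batch(lapply(ms$prep, `[[`, r)))
  lg <- redgraph:::model_loss_grads(ms$model, batches, c(1, 0, 1))
  for (r in c("A", "J")) {
    gnorm <- sqrt(sum(lg$grads$reps[[r]]$Wenc^2))
    expect_true(is.finite(gnorm))
    expect_gt(gnorm, 0)
  }
})
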