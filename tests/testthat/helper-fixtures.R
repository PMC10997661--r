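# Shared fixtures and independent oracles for the suite.

# O(N^2) pairwise-concordance AUROC (ties count one half)
bf_auroc <- function(score, y) {
  pos <- which(y == 1)
  neg <- which(y == 0)
  tot <- 0
  for (p in pos) for (n in neg) {
    tot <- tot + (score[p] > score[n]) + 0.5 * (score[p] == score[n])
  }
  tot / (length(pos) * length(neg))
}

# direct per-atom thresholded accuracy for one mask
bf_attacc <- function(att, mask) {
  y <- as.integer(seq_along(att) %in% mask)
  yhat <- as.integer(att >= 0.5)
  mean(y == yhat)
}

# hand-constructed reduced graph for interpretation algebra tests
fake_graph <- function(atom_map, n_atoms, representation = "J") {
  k <- length(atom_map)
  structure(list(
    representation = representation, smiles = "fake", n_atoms = n_atoms,
    node_features = matrix(0, k, 2,
                           dimnames = list(NULL, c("f1", "f2"))),
    edges = matrix(integer(0), ncol = 2),
    edge_features = NULL,
    atom_map = lapply(atom_map, as.integer),
    feature_names = c("f1", "f2")
  ), class = "molecular_graph")
}

# a small cached pool of generated molecules for invariant checks
generated_pool <- local({
  cache <- NULL
  function(n = 60) {
    if (is.null(cache) || nrow(cache$records) < n) {
      gen <- generate_dataset("Logic14", max(100, n), seed = 20260924)
      cache <<- gen
    }
    cache$records[seq_len(n), , drop = FALSE]
  }
})

# a tiny trained model on a 3MR dataset, cached across tests
tiny_trained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generate_dataset("3MR", 160, seed = 99)
      graphs <- build_graphs(gen$records$smiles, c("A", "J"))
      prep <- prepare_scheme_graphs(graphs, "A+J")
      split <- make_splits(gen$records, 0.2, 2, seed = 99)
      cfg <- model_config(embedding_dim = 12, epochs = 4, patience = 4,
                          learning_rate = 5e-3, batch_size = 32)
      fr <- train_fold(gen$records, prep, "A+J", split, 1, cfg)
      cache <<- list(gen = gen, graphs = prep, split = split,
                     config = cfg, fold = fr)
    }
    cache
  }
})

write_fixture_csv <- function(rows) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(rows, path, row.names = FALSE)
  path
}
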