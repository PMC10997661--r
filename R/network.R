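# The attention-readout graph network.
#
# Architecture, per representation: a linear node/edge encoder; an
# edge-aware GIN message-passing stage whose per-round aggregate
# (self + neighbour sum + encoded edge terms) is pushed through a linear
# layer with ReLU and then a gated recurrent (GRU) state update; and a
# readout stage in which a virtual super node, linked to every real node,
# attends over the nodes (single-head GAT-style attention) and updates its
# state with a GRU. The final virtual-node state is the molecule
# embedding; the final round's attention coefficients are the node
# attention used for interpretation. Embeddings of all representations in
# a scheme are concatenated and fed to a two-layer prediction head.
#
# There is no deep-learning runtime underneath: forward and backward
# passes are explicit matrix algebra over block-diagonal molecule batches
# (sparse adjacency via Matrix), with gradients derived analytically and
# verified against finite differences in the test suite.

#' Model configuration
#'
#' @param embedding_dim width of node and molecule embeddings (default 256).
#' @param mp_steps_atom message-passing rounds on the atom graph.
#' @param mp_steps_reduced message-passing rounds on reduced graphs
#'   (coarser graphs need fewer hops).
#' @param readout_steps attention-readout rounds of the virtual super node.
#' @param dropout dropout probability on the prediction head (training only).
#' @param task "classification" or "regression".
#' @param learning_rate,batch_size,epochs,patience,min_improvement Adam
#'   learning rate, minibatch size, epoch cap, early-stopping patience and
#'   minimum improvement counted as progress.
#' @param leaky_slope negative slope of the attention LeakyReLU.
#' @return a validated `model_config` list.
#' @export
model_config <- function(embedding_dim = 256, mp_steps_atom = 2,
                         mp_steps_reduced = 1, readout_steps = 2,
                         dropout = 0, task = "classification",
                         learning_rate = 1e-3, batch_size = 64,
                         epochs = 300, patience = 30,
                         min_improvement = 1e-5, leaky_slope = 0.2) {
  task <- match.arg(task, c("classification", "regression"))
  stopifnot(embedding_dim > 0, mp_steps_atom >= 1, mp_steps_reduced >= 1,
            readout_steps >= 1, dropout >= 0, dropout < 1,
            learning_rate > 0, batch_size >= 1, epochs >= 1, patience >= 1)
  structure(list(
    embedding_dim = as.integer(embedding_dim),
    mp_steps_atom = as.integer(mp_steps_atom),
    mp_steps_reduced = as.integer(mp_steps_reduced),
    readout_steps = as.integer(readout_steps),
    dropout = dropout, task = task, learning_rate = learning_rate,
    batch_size = as.integer(batch_size), epochs = as.integer(epochs),
    patience = as.integer(patience), min_improvement = min_improvement,
    leaky_slope = leaky_slope
  ), class = "model_config")
}

mp_steps_for <- function(config, rep) {
  if (rep == "A") config$mp_steps_atom else config$mp_steps_reduced
}

# --- initial pooling --------------------------------------------------------

#' Augment reduced-graph node features with pooled atom features
#'
#' In multi-graph schemes that include the atom graph, each reduced node's
#' feature vector is extended with the sum of the raw atom-graph features
#' of the atoms it covers, so the reduction does not fully discard
#' atom-level information.
#'
#' @param atom_graph the molecule's "A" `molecular_graph`.
#' @param reduced_graph a reduced `molecular_graph` of the same molecule.
#' @return the reduced graph with widened `node_features`.
#' @export
initial_pooling <- function(atom_graph, reduced_graph) {
  stopifnot(atom_graph$representation == "A",
            atom_graph$n_atoms == reduced_graph$n_atoms)
  af <- atom_graph$node_features
  pooled <- t(vapply(reduced_graph$atom_map, function(a) {
    if (any(a > nrow(af))) stop("atom_map index out of range")
    colSums(af[a, , drop = FALSE])
  }, numeric(ncol(af))))
  colnames(pooled) <- paste0("pooled_", colnames(af))
  reduced_graph$node_features <- cbind(reduced_graph$node_features, pooled)
  reduced_graph$feature_names <- colnames(reduced_graph$node_features)
  reduced_graph
}

#' Prepare per-molecule graphs for a scheme
#'
#' Selects the scheme's representations and applies [initial_pooling()] to
#' reduced graphs whenever the scheme contains the atom graph.
#'
#' @param graphs list (per molecule) of named `molecular_graph` lists.
#' @param scheme character vector of representation codes (or "A+J" label).
#' @return list (per molecule) of named prepared graphs.
#' @export
prepare_scheme_graphs <- function(graphs, scheme) {
  if (is.character(scheme) && length(scheme) == 1) {
    scheme <- parse_scheme(scheme)
  }
  lapply(graphs, function(gl) {
    if (is.null(gl)) return(NULL)
    missing <- setdiff(scheme, names(gl))
    if (length(missing) > 0) {
      stop("graphs missing representation(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    out <- gl[scheme]
    if ("A" %in% scheme && length(scheme) > 1) {
      for (r in setdiff(scheme, "A")) {
        out[[r]] <- initial_pooling(gl[["A"]], out[[r]])
      }
    }
    out
  })
}

# --- batching ---------------------------------------------------------------

# Stack single-representation graphs of several molecules into one
# block-diagonal disjoint graph.
graph_batch <- function(graphs) {
  stopifnot(length(graphs) > 0)
  sizes <- vapply(graphs, function(g) nrow(g$node_features), integer(1))
  if (any(sizes == 0)) stop("empty graph in batch", call. = FALSE)
  offsets <- c(0L, cumsum(sizes))
  N <- offsets[length(offsets)]
  X <- do.call(rbind, lapply(graphs, `[[`, "node_features"))
  node2mol <- rep(seq_along(graphs), sizes)
  ei <- integer(0); ej <- integer(0)
  has_edge_feats <- !is.null(graphs[[1]]$edge_features) &&
    ncol(graphs[[1]]$edge_features) > 0
  fe <- if (has_edge_feats) ncol(graphs[[1]]$edge_features) else 0L
  SE <- if (has_edge_feats) matrix(0, N, fe) else NULL
  deg <- numeric(N)
  for (k in seq_along(graphs)) {
    g <- graphs[[k]]
    if (nrow(g$edges) == 0) next
    a <- g$edges[, 1] + offsets[k]
    b <- g$edges[, 2] + offsets[k]
    ei <- c(ei, a, b); ej <- c(ej, b, a)
    deg[a] <- deg[a] + 1; deg[b] <- deg[b] + 1
    if (has_edge_feats) {
      for (e in seq_len(nrow(g$edges))) {
        SE[a[e], ] <- SE[a[e], ] + g$edge_features[e, ]
        SE[b[e], ] <- SE[b[e], ] + g$edge_features[e, ]
      }
    }
  }
  Agg <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(N, N))
  seg_end <- cumsum(sizes)
  seg_start <- seg_end - sizes + 1L
  structure(list(X = X, Agg = Agg, SE = SE, deg = deg,
                 node2mol = node2mol, sizes = sizes,
                 seg_start = seg_start, seg_end = seg_end,
                 n_mols = length(graphs), N = N), class = "graph_batch")
}

seg_softmax <- function(lin, batch) {
  mx <- vapply(seq_len(batch$n_mols), function(m)
    max(lin[batch$seg_start[m]:batch$seg_end[m]]), numeric(1))
  ex <- exp(lin - mx[batch$node2mol])
  tot <- as.numeric(rowsum(ex, batch$node2mol))
  ex / tot[batch$node2mol]
}

# --- parameters -------------------------------------------------------------

rand_mat <- function(nr, nc, fan_in) {
  s <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -s, s), nr, nc)
}

init_gru <- function(d) {
  list(Wz = rand_mat(d, d, d), Uz = rand_mat(d, d, d), bz = numeric(d),
       Wr = rand_mat(d, d, d), Ur = rand_mat(d, d, d), br = numeric(d),
       Wn = rand_mat(d, d, d), Un = rand_mat(d, d, d), bn = numeric(d))
}

init_rep_params <- function(node_width, edge_width, d) {
  p <- list(
    Wenc = rand_mat(d, node_width, node_width), benc = numeric(d),
    Wg = rand_mat(d, d, d), bg = numeric(d),
    gru_mp = init_gru(d),
    Wp = rand_mat(d, d, d), bp = numeric(d),
    att_a = runif(d, -1 / sqrt(d), 1 / sqrt(d)),
    att_b = runif(d, -1 / sqrt(d), 1 / sqrt(d)),
    gru_ro = init_gru(d)
  )
  if (edge_width > 0) {
    p$Wedge <- rand_mat(d, edge_width, edge_width)
    p$bedge <- numeric(d)
  }
  p
}

#' Initialise a model for a graph scheme
#'
#' Each representation gets its own encoder and backbone (no weight
#' sharing); the prediction head consumes the concatenated molecule
#' embeddings.
#'
#' @param scheme representation codes (e.g. `c("A","J")`) or label "A+J".
#' @param feature_widths named integer vector: node-feature width per
#'   representation (after initial pooling, where applicable).
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @param edge_width atom-graph edge-feature width (0 disables edge terms).
#' @return a `redgraph_model`.
#' @export
new_model <- function(scheme, feature_widths, config = model_config(),
                      seed = 1, edge_width = 6) {
  if (is.character(scheme) && length(scheme) == 1 && grepl("\\+", scheme)) {
    scheme <- parse_scheme(scheme)
  }
  stopifnot(all(scheme %in% names(feature_widths)))
  d <- config$embedding_dim
  with_seed(seed, {
    reps <- lapply(scheme, function(r) {
      init_rep_params(feature_widths[[r]],
                      if (r == "A") edge_width else 0L, d)
    })
    names(reps) <- scheme
    K <- length(scheme)
    head <- list(W1 = rand_mat(d, K * d, K * d), b1 = numeric(d),
                 W2 = runif(d, -1 / sqrt(d), 1 / sqrt(d)), b2 = 0)
    structure(list(scheme = scheme, config = config,
                   feature_widths = feature_widths,
                   params = list(reps = reps, head = head),
                   seed = as.integer(seed)),
              class = "redgraph_model")
  })
}

#' @export
print.redgraph_model <- function(x, ...) {
  cat(sprintf("<redgraph_model> scheme %s, %d-dim embeddings, task %s\n",
              scheme_label(x$scheme), x$config$embedding_dim,
              x$config$task))
  invisible(x)
}

# --- forward ----------------------------------------------------------------

add_bias <- function(M, b) sweep(M, 2, b, "+")
sigmoid <- function(x) 1 / (1 + exp(-x))

gru_fw <- function(g, h, p) {
  z <- sigmoid(add_bias(g %*% t(p$Wz) + h %*% t(p$Uz), p$bz))
  r <- sigmoid(add_bias(g %*% t(p$Wr) + h %*% t(p$Ur), p$br))
  rh <- r * h
  n <- tanh(add_bias(g %*% t(p$Wn) + rh %*% t(p$Un), p$bn))
  list(h = (1 - z) * n + z * h, z = z, r = r, n = n, rh = rh,
       g = g, hprev = h)
}

gru_bw <- function(dh, cache, p) {
  dz <- dh * (cache$hprev - cache$n)
  dn <- dh * (1 - cache$z)
  dhprev <- dh * cache$z
  dnpre <- dn * (1 - cache$n^2)
  dg <- dnpre %*% p$Wn
  drh <- dnpre %*% p$Un
  dr <- drh * cache$hprev
  dhprev <- dhprev + drh * cache$r
  drpre <- dr * cache$r * (1 - cache$r)
  dg <- dg + drpre %*% p$Wr
  dhprev <- dhprev + drpre %*% p$Ur
  dzpre <- dz * cache$z * (1 - cache$z)
  dg <- dg + dzpre %*% p$Wz
  dhprev <- dhprev + dzpre %*% p$Uz
  grads <- list(
    Wz = t(dzpre) %*% cache$g, Uz = t(dzpre) %*% cache$hprev,
    bz = colSums(dzpre),
    Wr = t(drpre) %*% cache$g, Ur = t(drpre) %*% cache$hprev,
    br = colSums(drpre),
    Wn = t(dnpre) %*% cache$g, Un = t(dnpre) %*% cache$rh,
    bn = colSums(dnpre))
  list(dg = dg, dh = dhprev, grads = grads)
}

rep_forward <- function(p, batch, steps, readout_steps, slope) {
  H <- add_bias(batch$X %*% t(p$Wenc), p$benc)
  H0 <- H
  ET <- NULL
  if (!is.null(batch$SE) && !is.null(p$Wedge)) {
    ET <- batch$SE %*% t(p$Wedge) + outer(batch$deg, p$bedge)
  }
  mp <- vector("list", steps)
  for (t in seq_len(steps)) {
    a <- H + as.matrix(batch$Agg %*% H)
    if (!is.null(ET)) a <- a + ET
    q <- add_bias(a %*% t(p$Wg), p$bg)
    g <- pmax(q, 0)
    cell <- gru_fw(g, H, p$gru_mp)
    mp[[t]] <- list(a = a, qmask = q > 0, cell = cell)
    H <- cell$h
  }
  Hp <- add_bias(H %*% t(p$Wp), p$bp)
  hterm <- drop(Hp %*% p$att_a)
  S <- rowsum(H, batch$node2mol) / batch$sizes
  dimnames(S) <- NULL
  S0 <- S
  ro <- vector("list", readout_steps)
  att <- NULL
  for (t in seq_len(readout_steps)) {
    sp <- add_bias(S %*% t(p$Wp), p$bp)
    pre <- unname(hterm + drop(sp %*% p$att_b)[batch$node2mol])
    lin <- ifelse(pre > 0, pre, slope * pre)
    att <- seg_softmax(lin, batch)
    C <- rowsum(att * Hp, batch$node2mol)
    dimnames(C) <- NULL
    cell <- gru_fw(C, S, p$gru_ro)
    ro[[t]] <- list(sp = sp, pre = pre, att = att, C = C, cell = cell,
                    Sprev = S)
    S <- cell$h
  }
  list(emb = S, att = att, cache = list(H0 = H0, H = H, Hp = Hp,
                                        hterm = hterm, S0 = S0, mp = mp,
                                        ro = ro, ET = ET))
}

rep_backward <- function(p, batch, cache, dEmb, steps, readout_steps,
                         slope) {
  zero_like <- function(x) array(0, dim = dim(x) %||% length(x))
  g <- list(Wenc = zero_like(p$Wenc), benc = numeric(length(p$benc)),
            Wg = zero_like(p$Wg), bg = numeric(length(p$bg)),
            gru_mp = lapply(p$gru_mp, zero_like),
            Wp = zero_like(p$Wp), bp = numeric(length(p$bp)),
            att_a = numeric(length(p$att_a)),
            att_b = numeric(length(p$att_b)),
            gru_ro = lapply(p$gru_ro, zero_like))
  if (!is.null(p$Wedge)) {
    g$Wedge <- zero_like(p$Wedge)
    g$bedge <- numeric(length(p$bedge))
  }
  n2m <- batch$node2mol
  dS <- dEmb
  dHp <- matrix(0, batch$N, ncol(cache$Hp))
  dhterm <- numeric(batch$N)
  for (t in rev(seq_len(readout_steps))) {
    st <- cache$ro[[t]]
    bw <- gru_bw(dS, st$cell, p$gru_ro)
    for (nm in names(bw$grads)) {
      g$gru_ro[[nm]] <- g$gru_ro[[nm]] + bw$grads[[nm]]
    }
    dC <- bw$dg
    dS <- bw$dh
    datt <- rowSums(cache$Hp * dC[n2m, , drop = FALSE])
    dHp <- dHp + st$att * dC[n2m, , drop = FALSE]
    inner <- as.numeric(rowsum(st$att * datt, n2m))
    dlin <- st$att * (datt - inner[n2m])
    dpre <- dlin * ifelse(st$pre > 0, 1, slope)
    dhterm <- dhterm + dpre
    segd <- as.numeric(rowsum(dpre, n2m))
    g$att_b <- g$att_b + drop(t(st$sp) %*% segd)
    dsp <- outer(segd, p$att_b)
    g$Wp <- g$Wp + t(dsp) %*% st$Sprev
    g$bp <- g$bp + colSums(dsp)
    dS <- dS + dsp %*% p$Wp
  }
  # S0 = segment mean of H
  dH <- (dS / batch$sizes)[n2m, , drop = FALSE]
  # hterm and Hp
  g$att_a <- g$att_a + drop(t(cache$Hp) %*% dhterm)
  dHp <- dHp + outer(dhterm, p$att_a)
  g$Wp <- g$Wp + t(dHp) %*% cache$H
  g$bp <- g$bp + colSums(dHp)
  dH <- dH + dHp %*% p$Wp
  dET <- NULL
  for (t in rev(seq_len(steps))) {
    st <- cache$mp[[t]]
    bw <- gru_bw(dH, st$cell, p$gru_mp)
    for (nm in names(bw$grads)) {
      g$gru_mp[[nm]] <- g$gru_mp[[nm]] + bw$grads[[nm]]
    }
    dq <- bw$dg * st$qmask
    g$Wg <- g$Wg + t(dq) %*% st$a
    g$bg <- g$bg + colSums(dq)
    da <- dq %*% p$Wg
    dH <- bw$dh + da + as.matrix(batch$Agg %*% da)
    if (!is.null(cache$ET)) {
      dET <- if (is.null(dET)) da else dET + da
    }
  }
  g$Wenc <- g$Wenc + t(dH) %*% batch$X
  g$benc <- g$benc + colSums(dH)
  if (!is.null(dET) && !is.null(p$Wedge)) {
    g$Wedge <- g$Wedge + t(dET) %*% batch$SE
    g$bedge <- g$bedge + drop(t(dET) %*% batch$deg)
  }
  g
}

model_forward_batch <- function(model, batches, train = FALSE,
                                dropout_mask = NULL) {
  cfg <- model$config
  outs <- lapply(model$scheme, function(r) {
    rep_forward(model$params$reps[[r]], batches[[r]],
                mp_steps_for(cfg, r), cfg$readout_steps, cfg$leaky_slope)
  })
  names(outs) <- model$scheme
  E <- do.call(cbind, lapply(outs, `[[`, "emb"))
  head <- model$params$head
  U <- pmax(add_bias(E %*% t(head$W1), head$b1), 0)
  mask <- NULL
  if (train && cfg$dropout > 0) {
    mask <- if (is.null(dropout_mask)) {
      matrix(runif(length(U)) >= cfg$dropout, nrow(U)) / (1 - cfg$dropout)
    } else {
      dropout_mask
    }
    Ud <- U * mask
  } else {
    Ud <- U
  }
  logit <- drop(Ud %*% head$W2) + head$b2
  pred <- if (cfg$task == "classification") sigmoid(logit) else logit
  list(logit = logit, pred = pred, E = E, U = U, Ud = Ud, mask = mask,
       outs = outs)
}

model_loss_grads <- function(model, batches, y, train = TRUE) {
  cfg <- model$config
  fwd <- model_forward_batch(model, batches, train = train)
  B <- length(y)
  if (cfg$task == "classification") {
    pr <- pmin(pmax(fwd$pred, 1e-12), 1 - 1e-12)
    loss <- -mean(y * log(pr) + (1 - y) * log(1 - pr))
    dlogit <- (fwd$pred - y) / B
  } else {
    loss <- mean((fwd$pred - y)^2)
    dlogit <- 2 * (fwd$pred - y) / B
  }
  head <- model$params$head
  gW2 <- drop(t(fwd$Ud) %*% dlogit)
  gb2 <- sum(dlogit)
  dUd <- outer(dlogit, head$W2)
  dU <- if (!is.null(fwd$mask)) dUd * fwd$mask else dUd
  dpre <- dU * (fwd$U > 0)
  gW1 <- t(dpre) %*% fwd$E
  gb1 <- colSums(dpre)
  dE <- dpre %*% head$W1
  d <- cfg$embedding_dim
  grads_reps <- list()
  for (k in seq_along(model$scheme)) {
    r <- model$scheme[k]
    dEmb <- dE[, ((k - 1) * d + 1):(k * d), drop = FALSE]
    grads_reps[[r]] <- rep_backward(
      model$params$reps[[r]], batches[[r]], fwd$outs[[r]]$cache, dEmb,
      mp_steps_for(cfg, r), cfg$readout_steps, cfg$leaky_slope)
  }
  list(loss = loss,
       grads = list(reps = grads_reps,
                    head = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)),
       pred = fwd$pred)
}

# --- exported single-molecule operations ------------------------------------

single_batch <- function(model, graphs_one) {
  stopifnot(all(model$scheme %in% names(graphs_one)))
  lapply(setNames(model$scheme, model$scheme),
         function(r) graph_batch(graphs_one[r]))
}

#' Initial node encoding of a graph under a model
#'
#' @param model a `redgraph_model`.
#' @param graph a `molecular_graph` of a representation in the model scheme.
#' @return matrix of per-node initial embeddings.
#' @export
encode_nodes <- function(model, graph) {
  r <- graph$representation
  p <- model$params$reps[[r]]
  if (is.null(p)) stop("representation not in model scheme", call. = FALSE)
  if (ncol(graph$node_features) != ncol(p$Wenc)) {
    stop("node feature width does not match model vocabulary",
         call. = FALSE)
  }
  add_bias(graph$node_features %*% t(p$Wenc), p$benc)
}

#' Final node embeddings of a graph under a model
#' @inheritParams encode_nodes
#' @return matrix of per-node embeddings after message passing.
#' @export
embed_nodes <- function(model, graph) {
  r <- graph$representation
  p <- model$params$reps[[r]]
  if (is.null(p)) stop("representation not in model scheme", call. = FALSE)
  batch <- graph_batch(list(graph))
  out <- rep_forward(p, batch, mp_steps_for(model$config, r),
                     model$config$readout_steps, model$config$leaky_slope)
  out$cache$H
}

#' Molecule readout: embedding and node attention
#' @inheritParams encode_nodes
#' @return list with `embedding` (vector) and `attention` (per-node vector
#'   summing to one).
#' @export
readout_molecule <- function(model, graph) {
  r <- graph$representation
  p <- model$params$reps[[r]]
  if (is.null(p)) stop("representation not in model scheme", call. = FALSE)
  if (nrow(graph$node_features) == 0) stop("empty graph", call. = FALSE)
  batch <- graph_batch(list(graph))
  out <- rep_forward(p, batch, mp_steps_for(model$config, r),
                     model$config$readout_steps, model$config$leaky_slope)
  list(embedding = drop(out$emb), attention = out$att)
}

#' Full forward pass for one molecule
#'
#' @param model a `redgraph_model`.
#' @param graphs_one named list of prepared `molecular_graph`s covering the
#'   model scheme (see [prepare_scheme_graphs()]).
#' @return list with `prediction`, per-representation raw `attention`, and
#'   per-representation molecule `embeddings`.
#' @export
forward_model <- function(model, graphs_one) {
  batches <- single_batch(model, graphs_one)
  fwd <- model_forward_batch(model, batches, train = FALSE)
  list(prediction = unname(fwd$pred),
       attention = lapply(fwd$outs, `[[`, "att"),
       embeddings = lapply(fwd$outs, function(o) drop(o$emb)))
}

#' Predict for many molecules
#'
#' @param model a `redgraph_model`.
#' @param graphs list (per molecule) of prepared named graph lists.
#' @param with_attention also return per-molecule, per-representation raw
#'   attention vectors.
#' @return numeric predictions, or a list with `prediction` and `attention`.
#' @export
predict_molecules <- function(model, graphs, with_attention = FALSE) {
  batches <- lapply(setNames(model$scheme, model$scheme), function(r)
    graph_batch(lapply(graphs, `[[`, r)))
  fwd <- model_forward_batch(model, batches, train = FALSE)
  if (!with_attention) return(fwd$pred)
  att <- lapply(setNames(model$scheme, model$scheme), function(r)
    split(fwd$outs[[r]]$att, batches[[r]]$node2mol))
  list(prediction = fwd$pred,
       attention = lapply(seq_along(graphs), function(i)
         lapply(att, `[[`, i)))
}

# --- parameter tree utilities & Adam ----------------------------------------

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- lapply(seq_along(a), function(i) tree_map2(f, a[[i]], b[[i]]))
    names(out) <- names(a)
    out
  } else {
    f(a, b)
  }
}

tree_zero <- function(a) {
  if (is.list(a)) lapply(a, tree_zero) else a * 0
}

adam_state <- function(params) {
  list(m = tree_zero(params), v = tree_zero(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g,
                       state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                       state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}
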