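# Multilayer graph isomorphism network over the hybrid graph. Each layer
# computes mlp((1 + eps) h_v + sum_{j in N(v)} h_j); the per-layer MLP is a
# two-layer perceptron with row-wise layer normalization and ReLU. The
# readout concatenates the central node's final state with the mean over
# all nodes, and a fully connected head outputs the graph-based affinity.

#' GIN configuration
#'
#' @param n_layers number of message-passing layers (>= 2 so drug and
#'   protein nodes can exchange information through the central node).
#' @param epsilon the self-weighting hyperparameter of the GIN update.
#' @param learn_epsilon make epsilon a trained parameter (per layer).
#' @param mlp_hidden hidden width of each layer's two-layer perceptron.
#' @param dim output width of every layer.
#' @param readout `"central+mean"`, `"central"` or `"mean"`.
#' @param head_dims hidden widths of the prediction head.
#' @return a `gin_config` list.
#' @export
gin_config <- function(n_layers = 3L, epsilon = 0, learn_epsilon = FALSE,
                       mlp_hidden = 32L, dim = 32L,
                       readout = c("central+mean", "central", "mean"),
                       head_dims = c(32L)) {
  readout <- match.arg(readout)
  stopifnot(n_layers >= 1, is.finite(epsilon))
  structure(list(n_layers = as.integer(n_layers), epsilon = epsilon,
                 learn_epsilon = isTRUE(learn_epsilon),
                 mlp_hidden = as.integer(mlp_hidden), dim = as.integer(dim),
                 readout = readout, head_dims = as.integer(head_dims)),
            class = "gin_config")
}

#' Initialize GIN parameters
#'
#' @param cfg a [gin_config()].
#' @param in_dim width of the input node features (the encoder width).
#' @param seed RNG seed.
#' @return flat named list of parameter matrices.
#' @export
init_gnn_params <- function(cfg, in_dim, seed = 1L) {
  set.seed(derive_seed(seed, 29L))
  p <- list()
  d_in <- in_dim
  for (l in seq_len(cfg$n_layers)) {
    p[[paste0("gin", l, "_W1")]] <- nn_init_mat(d_in, cfg$mlp_hidden)
    p[[paste0("gin", l, "_b1")]] <- nn_zeros(1L, cfg$mlp_hidden)
    p[[paste0("gin", l, "_W2")]] <- nn_init_mat(cfg$mlp_hidden, cfg$dim)
    p[[paste0("gin", l, "_b2")]] <- nn_zeros(1L, cfg$dim)
    if (cfg$learn_epsilon)
      p[[paste0("gin", l, "_eps")]] <- matrix(cfg$epsilon, 1L, 1L)
    d_in <- cfg$dim
  }
  ro_dim <- if (cfg$readout == "central+mean") 2L * cfg$dim else cfg$dim
  c(p, nn_init_mlp("gnn_fc", c(ro_dim, cfg$head_dims, 1L)))
}

#' One GIN aggregation layer
#'
#' Computes `mlp((1 + epsilon) * h_v + sum_{j in N(v)} h_j)` for every node.
#'
#' @param features node feature matrix (nodes x width) or vector of scalar
#'   features.
#' @param graph a `hybrid_graph` or a symmetric binary adjacency matrix.
#' @param epsilon self-weighting scalar.
#' @param mlp function applied row-wise to the aggregated features
#'   (default identity).
#' @return matrix of updated node features.
#' @export
gin_layer <- function(features, graph, epsilon = 0, mlp = identity) {
  a <- if (inherits(graph, "hybrid_graph")) hybrid_adjacency(graph) else
    as.matrix(graph)
  if (is.null(dim(features))) features <- matrix(features, ncol = 1L)
  if (nrow(features) != nrow(a))
    stop("feature row count does not match graph node count")
  agg <- (1 + epsilon) * features + a %*% features
  mlp(agg)
}

# --- batched trained forward/backward --------------------------------------

# A: sparse symmetric adjacency over the stacked batch; X: stacked node
# features; graph_id: integer graph membership per row; central_rows:
# 1-based row of each graph's central node.
#' @noRd
gnn_forward_batch <- function(A, X, graph_id, central_rows, cfg, params) {
  counts <- as.vector(table(graph_id))
  caches <- vector("list", cfg$n_layers)
  h <- X
  for (l in seq_len(cfg$n_layers)) {
    eps <- if (cfg$learn_epsilon) params[[paste0("gin", l, "_eps")]][1, 1]
           else cfg$epsilon
    S <- (1 + eps) * h + as.matrix(A %*% h)
    Z1 <- nn_addb(S %*% params[[paste0("gin", l, "_W1")]],
                  params[[paste0("gin", l, "_b1")]])
    ln <- nn_layernorm_rows(Z1)
    R <- nn_relu(ln$y)
    X2 <- nn_addb(R %*% params[[paste0("gin", l, "_W2")]],
                  params[[paste0("gin", l, "_b2")]])
    hnext <- if (l < cfg$n_layers) nn_relu(X2) else X2
    caches[[l]] <- list(Xin = h, S = S, ln = ln, R = R, X2 = X2, eps = eps)
    h <- hnext
  }
  M <- rowsum(h, graph_id) / counts
  O <- switch(cfg$readout,
              "central+mean" = cbind(h[central_rows, , drop = FALSE], M),
              "central" = h[central_rows, , drop = FALSE],
              "mean" = M)
  n_fc <- length(cfg$head_dims) + 1L
  head <- nn_mlp_forward(O, params, "gnn_fc", n_fc)
  list(pred = as.vector(head$out), node_states = h, O = O, M = M,
       head = head, caches = caches, counts = counts,
       graph_id = graph_id, central_rows = central_rows, A = A)
}

#' @noRd
gnn_backward_batch <- function(dpred, fw, cfg, params) {
  grads <- list()
  n_fc <- length(cfg$head_dims) + 1L
  hb <- nn_mlp_backward(matrix(dpred, ncol = 1L), fw$head, params,
                        "gnn_fc", n_fc, grads)
  grads <- hb$grads
  dO <- hb$dx
  d <- cfg$dim
  n_nodes <- nrow(fw$node_states)
  dh <- matrix(0, n_nodes, d)
  add_central <- function(dc) {
    dh[fw$central_rows, ] <<- dh[fw$central_rows, , drop = FALSE] + dc
  }
  add_mean <- function(dm) {
    dh <<- dh + (dm / fw$counts)[fw$graph_id, , drop = FALSE]
  }
  switch(cfg$readout,
         "central+mean" = {
           add_central(dO[, seq_len(d), drop = FALSE])
           add_mean(dO[, d + seq_len(d), drop = FALSE])
         },
         "central" = add_central(dO),
         "mean" = add_mean(dO))
  for (l in rev(seq_len(cfg$n_layers))) {
    cc <- fw$caches[[l]]
    dX2 <- if (l < cfg$n_layers) dh * (cc$X2 > 0) else dh
    W2n <- paste0("gin", l, "_W2"); b2n <- paste0("gin", l, "_b2")
    W1n <- paste0("gin", l, "_W1"); b1n <- paste0("gin", l, "_b1")
    grads[[W2n]] <- (grads[[W2n]] %||% 0) + crossprod(cc$R, dX2)
    grads[[b2n]] <- (grads[[b2n]] %||% 0) + matrix(colSums(dX2), 1L)
    dR <- dX2 %*% t(params[[W2n]])
    dY <- dR * (cc$ln$y > 0)
    dZ1 <- nn_layernorm_rows_bwd(dY, cc$ln$y, cc$ln$sd)
    grads[[W1n]] <- (grads[[W1n]] %||% 0) + crossprod(cc$S, dZ1)
    grads[[b1n]] <- (grads[[b1n]] %||% 0) + matrix(colSums(dZ1), 1L)
    dS <- dZ1 %*% t(params[[W1n]])
    if (cfg$learn_epsilon) {
      en <- paste0("gin", l, "_eps")
      grads[[en]] <- (grads[[en]] %||% 0) +
        matrix(sum(dS * cc$Xin), 1L, 1L)
    }
    dh <- (1 + cc$eps) * dS + as.matrix(fw$A %*% dS)
  }
  list(grads = grads, dX = dh)
}

#' Run the GIN over one hybrid graph
#'
#' Node features are stacked protein-first, drug second, central last, the
#' order in which [build_hybrid_graph()] indexes nodes.
#'
#' @param graph a `hybrid_graph`.
#' @param feats a `node_feature_set` from [extract_node_features()].
#' @param cfg a [gin_config()].
#' @param params GNN parameters from [init_gnn_params()].
#' @return list with `node_states` (final per-node states), `embedding`
#'   (the readout vector O_g) and `pred` (graph-based affinity).
#' @export
gnn_forward <- function(graph, feats, cfg, params) {
  stopifnot(inherits(graph, "hybrid_graph"),
            inherits(feats, "node_feature_set"))
  X <- rbind(feats$protein_features, feats$drug_features,
             matrix(feats$central_feature, 1L))
  n <- graph$n_protein + graph$n_drug + 1L
  if (nrow(X) != n) stop("node feature rows do not match graph size")
  A <- hybrid_adjacency_sparse(graph$edges, n)
  fw <- gnn_forward_batch(A, X, rep(1L, n), n, cfg, params)
  list(node_states = fw$node_states, embedding = as.vector(fw$O),
       pred = fw$pred[1])
}

#' Graph-based affinity prediction from a readout embedding
#'
#' @param O_g readout vector (or matrix, one row per graph).
#' @param cfg a [gin_config()].
#' @param params GNN parameters.
#' @return numeric vector of predictions.
#' @export
graph_predict <- function(O_g, cfg, params) {
  if (is.null(dim(O_g))) O_g <- matrix(O_g, nrow = 1L)
  if (!all(is.finite(O_g))) stop("non-finite graph embedding")
  n_fc <- length(cfg$head_dims) + 1L
  as.vector(nn_mlp_forward(O_g, params, "gnn_fc", n_fc)$out)
}
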