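test_that("gin_layer matches hand-computed aggregations", {
  # path graph, unit scalar features, identity mlp: 1 + degree
  a_path <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3)
  out <- gin_layer(rep(1, 3), a_path, epsilon = 0)
  expect_equal(as.vector(out), c(2, 3, 2))
  # isolated node: (1 + eps) * h
  out_iso <- gin_layer(matrix(c(2, -1), 1), matrix(0, 1, 1), epsilon = 0.5)
  expect_equal(as.vector(out_iso), 1.5 * c(2, -1))
  # custom mlp is applied to the aggregate
  out_sq <- gin_layer(rep(1, 3), a_path, epsilon = 0, mlp = function(x) x^2)
  expect_equal(as.vector(out_sq), c(4, 9, 4))
  expect_error(gin_layer(rep(1, 2), a_path), "row count")
})

test_that("gin_layer equals a brute-force per-node loop on random graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:10, 1)
    a <- matrix(rbinom(n * n, 1, 0.4), n)
    a <- 1 * ((a + t(a)) > 0)
    diag(a) <- 0
    x <- matrix(rnorm(n * 3), n)
    for (eps in c(0, 0.5, -0.3)) {
      got <- gin_layer(x, a, epsilon = eps)
      want <- x * 0
      for (v in seq_len(n)) {
        nb <- which(a[v, ] == 1)
        want[v, ] <- (1 + eps) * x[v, ] +
          if (length(nb)) colSums(x[nb, , drop = FALSE]) else 0
      }
      expect_equal(unname(as.matrix(got)), unname(want), tolerance = 1e-6)
    }
  }
})

make_feats <- function(hg, width, seed = 1) {
  set.seed(seed)
  structure(list(
    protein_features = matrix(rnorm(hg$n_protein * width), hg$n_protein),
    drug_features = matrix(rnorm(hg$n_drug * width), hg$n_drug),
    central_feature = rnorm(width)), class = "node_feature_set")
}

test_that("gnn_forward composes gin layers and predicts deterministically", {
  pr <- random_graph_pair(5)
  hg <- build_hybrid_graph(pr$gp, pr$gd)
  cfg <- gin_config(n_layers = 2, mlp_hidden = 6, dim = 5, head_dims = 4)
  params <- init_gnn_params(cfg, 4L, seed = 2)
  feats <- make_feats(hg, 4L)
  out1 <- gnn_forward(hg, feats, cfg, params)
  out2 <- gnn_forward(hg, feats, cfg, params)
  expect_identical(out1$pred, out2$pred)
  expect_identical(nrow(out1$node_states), hg$n_protein + hg$n_drug + 1L)
  expect_length(out1$embedding, 2L * cfg$dim)
  # zeroed head final layer forces the bias
  pz <- params
  pz$gnn_fc2_W[] <- 0
  pz$gnn_fc2_b[] <- -1.5
  expect_equal(graph_predict(out1$embedding, cfg, pz), -1.5)
  expect_error(graph_predict(c(NA, out1$embedding[-1]), cfg, params),
               "non-finite")
})

test_that("relabeling drug atoms permutes states and leaves the prediction unchanged", {
  for (seed in c(2, 9)) {
    pr <- random_graph_pair(seed)
    hg <- build_hybrid_graph(pr$gp, pr$gd)
    nd <- hg$n_drug
    if (nd < 2) next
    cfg <- gin_config(n_layers = 3, mlp_hidden = 6, dim = 5, head_dims = 4)
    params <- init_gnn_params(cfg, 4L, seed = 3)
    feats <- make_feats(hg, 4L, seed)
    set.seed(seed + 100)
    perm <- sample(nd)
    gd2 <- structure(list(n_atoms = nd, edges = {
      e <- pr$gd$edges
      e2 <- cbind(match(e[, 1] + 1L, perm) - 1L,
                  match(e[, 2] + 1L, perm) - 1L)
      cbind(pmin(e2[, 1], e2[, 2]), pmax(e2[, 1], e2[, 2]))
    }), class = "drug_graph")
    hg2 <- build_hybrid_graph(pr$gp, gd2)
    feats2 <- feats
    feats2$drug_features <- feats$drug_features[perm, , drop = FALSE]
    # feats2 row i is original atom perm[i]; adjacency relabeled to match
    out <- gnn_forward(hg, feats, cfg, params)
    out2 <- gnn_forward(hg2, feats2, cfg, params)
    expect_equal(out2$pred, out$pred, tolerance = 1e-5)
    np <- hg$n_protein
    expect_equal(out2$node_states[np + seq_len(nd), ],
                 out$node_states[np + perm, ], tolerance = 1e-5)
  }
})

test_that("information reaches the central node in one layer and crosses molecules in two", {
  pr <- random_graph_pair(4)
  hg <- build_hybrid_graph(pr$gp, pr$gd)
  np <- hg$n_protein
  feats <- make_feats(hg, 4L)
  params1 <- init_gnn_params(gin_config(n_layers = 1, mlp_hidden = 6,
                                        dim = 5, head_dims = 4), 4L, 2)
  cfg1 <- gin_config(n_layers = 1, mlp_hidden = 6, dim = 5, head_dims = 4)
  feats_p <- feats
  feats_p$drug_features[1, 1] <- feats_p$drug_features[1, 1] + 0.37
  base <- gnn_forward(hg, feats, cfg1, params1)
  pert <- gnn_forward(hg, feats_p, cfg1, params1)
  central <- np + hg$n_drug + 1L
  expect_gt(max(abs(pert$node_states[central, ] -
                      base$node_states[central, ])), 0)
  # after one layer a protein node is still unaffected (hop distance 2)
  expect_equal(pert$node_states[1L, ], base$node_states[1L, ],
               tolerance = 1e-12)
  # after two layers the perturbation has crossed via the central node
  cfg2 <- gin_config(n_layers = 2, mlp_hidden = 6, dim = 5, head_dims = 4)
  params2 <- init_gnn_params(cfg2, 4L, 2)
  base2 <- gnn_forward(hg, feats, cfg2, params2)
  pert2 <- gnn_forward(hg, feats_p, cfg2, params2)
  expect_gt(max(abs(pert2$node_states[1L, ] - base2$node_states[1L, ])), 0)
})

test_that("analytic GNN gradients match finite differences", {
  ns <- asNamespace("hybridDTA")
  pr1 <- random_graph_pair(7)
  pr2 <- random_graph_pair(8)
  hg1 <- build_hybrid_graph(pr1$gp, pr1$gd)
  hg2 <- build_hybrid_graph(pr2$gp, pr2$gd)
  n1 <- hg1$n_protein + hg1$n_drug + 1L
  n2 <- hg2$n_protein + hg2$n_drug + 1L
  cfg <- gin_config(n_layers = 2, epsilon = 0.1, learn_epsilon = TRUE,
                    mlp_hidden = 5, dim = 4, head_dims = 6)
  params <- init_gnn_params(cfg, 3L, seed = 5)
  set.seed(11)
  X <- matrix(rnorm((n1 + n2) * 3), n1 + n2)
  A <- ns$hybrid_adjacency_sparse(rbind(hg1$edges, hg2$edges + n1), n1 + n2)
  gid <- rep(1:2, c(n1, n2))
  central <- c(n1, n1 + n2)
  y <- c(5, 7)
  loss <- function(p) {
    fw <- ns$gnn_forward_batch(A, X, gid, central, cfg, p)
    mean((fw$pred - y)^2)
  }
  fw <- ns$gnn_forward_batch(A, X, gid, central, cfg, params)
  grads <- ns$gnn_backward_batch(2 * (fw$pred - y) / 2, fw, cfg, params)$grads
  eps <- 1e-6
  set.seed(1)
  for (nm in names(params)) {
    pick <- sample(length(params[[nm]]), min(3, length(params[[nm]])))
    for (k in pick) {
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- params; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (loss(p2) - loss(p3)) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-4,
                   label = paste("grad", nm, k))
    }
  }
})
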