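test_that("encoding preserves length and is deterministic", {
  g <- tiny_generator()
  ts <- tokenize_protein("MKVWACD", g$vocab_p)
  h1 <- encode(ts, g$cfg, g$params)
  h2 <- encode(ts, g$cfg, g$params)
  expect_identical(nrow(h1), length(ts$tokens))
  expect_identical(ncol(h1), g$cfg$width)
  expect_identical(unclass(h1), unclass(h2))
  expect_true(all(is.finite(h1)))
})

test_that("the encoder is bidirectional: a token change propagates both ways", {
  g <- tiny_generator()
  h1 <- encode(tokenize_protein("ACDEFG", g$vocab_p), g$cfg, g$params)
  h2 <- encode(tokenize_protein("ACDKFG", g$vocab_p), g$cfg, g$params)
  # residue 4 changed (token row 5): rows before AND after must differ
  expect_gt(max(abs(h1[2, ] - h2[2, ])), 0)   # left of the change
  expect_gt(max(abs(h1[7, ] - h2[7, ])), 0)   # right of the change
})

test_that("out-of-range token ids are rejected", {
  g <- tiny_generator()
  ts <- tokenize_protein("MKV", g$vocab_p)
  ts$ids[2] <- 10000L
  expect_error(encode(ts, g$cfg, g$params), "out of vocabulary")
})

test_that("attention weights reproduce independent softmax arithmetic", {
  g <- tiny_generator()
  set.seed(1)
  h <- matrix(rnorm(7 * g$cfg$width), 7)
  out <- attention_pool(h, g$cfg, g$params, kind = "protein")
  w <- g$params$p_att_w
  for (k in seq_len(g$cfg$n_heads)) {
    s <- as.vector(h %*% w[, k]) / g$cfg$d_k
    expect_equal(out$weights[, k], exp(s) / sum(exp(s)), tolerance = 1e-6)
  }
  expect_equal(colSums(out$weights), rep(1, g$cfg$n_heads), tolerance = 1e-6)
  # pooled vector is the weight-averaged embedding, heads concatenated
  expect_equal(out$pooled,
               as.vector(vapply(seq_len(g$cfg$n_heads), function(k)
                 colSums(out$weights[, k] * h), numeric(g$cfg$width))),
               tolerance = 1e-10)
})

test_that("constant inputs give uniform attention; two-row case matches a hand softmax", {
  g <- tiny_generator()
  hc <- matrix(1, 5, g$cfg$width)
  out <- attention_pool(hc, g$cfg, g$params, kind = "drug")
  expect_equal(unname(out$weights), matrix(1 / 5, 5, g$cfg$n_heads),
               tolerance = 1e-10)

  h2 <- matrix(rnorm(2 * g$cfg$width), 2)
  out2 <- attention_pool(h2, g$cfg, g$params, kind = "drug")
  s <- (h2 %*% g$params$d_att_w[, 1]) / g$cfg$d_k
  expect_equal(out2$weights[1, 1], exp(s[1]) / (exp(s[1]) + exp(s[2])),
               tolerance = 1e-12)

  expect_error(attention_pool(matrix(0, 0, g$cfg$width), g$cfg, g$params,
                              kind = "drug"), "empty")
})

test_that("cross attention pools over the joint position axis", {
  g <- tiny_generator()
  h_d <- encode(tokenize_drug("CCO", g$vocab_d), g$cfg, g$params)
  h_p <- encode(tokenize_protein("MKVW", g$vocab_p), g$cfg, g$params)
  out <- cross_pool(h_d, h_p, g$cfg, g$params)
  expect_identical(nrow(out$weights), nrow(h_d) + nrow(h_p))
  expect_true(all(out$weights >= 0))
  expect_equal(colSums(out$weights), rep(1, g$cfg$n_heads), tolerance = 1e-6)
  expect_error(cross_pool(h_d, h_p[, 1:3], g$cfg, g$params), "width")
})

test_that("pooled outputs are invariant to batch padding", {
  g <- tiny_generator()
  ns <- asNamespace("hybridDTA")
  tok_d <- list(tokenize_drug("CCO", g$vocab_d),
                tokenize_drug("CC(=O)NC", g$vocab_d))
  tok_p <- list(tokenize_protein("MKVW", g$vocab_p),
                tokenize_protein("ACDEFGAC", g$vocab_p))
  batch <- list(
    d_ids = ns$pad_ids(lapply(tok_d, `[[`, "ids"),
                       g$vocab_d$token_to_id[["[PAD]"]]),
    d_len = lengths(lapply(tok_d, `[[`, "ids")),
    p_ids = ns$pad_ids(lapply(tok_p, `[[`, "ids"),
                       g$vocab_p$token_to_id[["[PAD]"]]),
    p_len = lengths(lapply(tok_p, `[[`, "ids")))
  fw <- ns$gen_forward(batch, g$params, g$cfg)
  # record 1 is padded inside the batch; a solo forward must agree exactly
  h_d <- encode(tok_d[[1]], g$cfg, g$params)
  h_p <- encode(tok_p[[1]], g$cfg, g$params)
  solo_d <- attention_pool(h_d, g$cfg, g$params, kind = "drug")
  solo_c <- cross_pool(h_d, h_p, g$cfg, g$params)
  expect_equal(fw$Opool_d[1, ], solo_d$pooled, tolerance = 1e-12)
  expect_equal(fw$Opool_c[1, ], solo_c$pooled, tolerance = 1e-12)
  expect_equal(fw$pred[1],
               sequence_predict(solo_d$mixed,
                                attention_pool(h_p, g$cfg, g$params,
                                               kind = "protein")$mixed,
                                solo_c$mixed, g$cfg, g$params),
               tolerance = 1e-12)
})

test_that("sequence head is deterministic and analytically forceable", {
  g <- tiny_generator()
  D <- g$cfg$width
  od <- rnorm(D); op <- rnorm(D); oc <- rnorm(D)
  p1 <- sequence_predict(od, op, oc, g$cfg, g$params)
  expect_identical(p1, sequence_predict(od, op, oc, g$cfg, g$params))
  # zero the final layer: output is exactly the bias
  pz <- g$params
  pz$seq_fc2_W[] <- 0
  pz$seq_fc2_b[] <- 4.25
  expect_equal(sequence_predict(od, op, oc, g$cfg, pz), 4.25)
  # batch order preserved
  Z <- matrix(rnorm(3 * D), 3)
  pb <- sequence_predict(Z, Z, Z, g$cfg, g$params)
  expect_length(pb, 3L)
  expect_equal(pb[2], sequence_predict(Z[2, ], Z[2, ], Z[2, ], g$cfg,
                                       g$params))
  expect_error(sequence_predict(od * NA, op, oc, g$cfg, g$params),
               "non-finite")
})

test_that("node features are gathered by map, normalized, and averaged into the central feature", {
  g <- tiny_generator()
  tok_d <- tokenize_drug("CCO", g$vocab_d)
  tok_p <- tokenize_protein("MKVW", g$vocab_p)
  h_d <- encode(tok_d, g$cfg, g$params)
  h_p <- encode(tok_p, g$cfg, g$params)
  nf <- extract_node_features(h_d, h_p)
  expect_identical(nrow(nf$drug_features), 3L)
  expect_identical(nrow(nf$protein_features), 4L)
  rows <- rbind(nf$drug_features, nf$protein_features)
  expect_true(all(abs(rowMeans(rows)) < 1e-5))
  expect_true(all(abs(apply(rows, 1, function(r) mean((r - mean(r))^2)) - 1)
                  < 1e-3))
  # forced arithmetic with normalization disabled
  fake_tok <- function(kind, pos) {
    structure(list(tokens = NULL, ids = NULL,
                   node_index_map = stats::setNames(0L, as.character(pos)),
                   kind = kind), class = "dta_tokseq")
  }
  hd0 <- rbind(c(2, 2), c(0, 0))
  hp0 <- rbind(c(0, 0), c(1, 1))
  nf0 <- extract_node_features(hd0, hp0, fake_tok("drug", 2),
                               fake_tok("protein", 2), normalize = FALSE)
  expect_equal(nf0$central_feature, c(1, 1))
  # out-of-range map
  expect_error(extract_node_features(hd0, hp0, fake_tok("drug", 5),
                                     fake_tok("protein", 2)),
               "exceeds")
})

test_that("analytic generator gradients match finite differences", {
  g <- tiny_generator()
  ns <- asNamespace("hybridDTA")
  tok_d <- list(tokenize_drug("CCO", g$vocab_d),
                tokenize_drug("c1ccccc1Cl", g$vocab_d))
  tok_p <- list(tokenize_protein("MKVW", g$vocab_p),
                tokenize_protein("GGSAERV", g$vocab_p))
  batch <- list(
    d_ids = ns$pad_ids(lapply(tok_d, `[[`, "ids"),
                       g$vocab_d$token_to_id[["[PAD]"]]),
    d_len = lengths(lapply(tok_d, `[[`, "ids")),
    p_ids = ns$pad_ids(lapply(tok_p, `[[`, "ids"),
                       g$vocab_p$token_to_id[["[PAD]"]]),
    p_len = lengths(lapply(tok_p, `[[`, "ids")),
    y = c(5.2, 6.7))
  loss <- function(params) {
    fw <- ns$gen_forward(batch, params, g$cfg)
    mean((fw$pred - batch$y)^2)
  }
  fw <- ns$gen_forward(batch, g$params, g$cfg)
  grads <- ns$gen_backward(2 * (fw$pred - batch$y) / 2, fw, g$params, g$cfg)
  eps <- 1e-6
  set.seed(42)
  for (nm in names(g$params)) {
    pick <- sample(length(g$params[[nm]]), min(3, length(g$params[[nm]])))
    for (k in pick) {
      p2 <- g$params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- g$params; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (loss(p2) - loss(p3)) / (2 * eps)
      expect_equal(grads[[nm]][k], num, tolerance = 1e-4,
                   label = paste("grad", nm, k))
    }
  }
  # gradient reaches both encoders (no detached graph)
  expect_gt(max(abs(grads$d_emb)), 0)
  expect_gt(max(abs(grads$p_emb)), 0)
  expect_gt(max(abs(grads$d_Wf)), 0)
  expect_gt(max(abs(grads$p_Wb)), 0)
})
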