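# Fast training-mechanics tests; the full planted-signal recovery study
# lives in test-acceptance.R.

test_that("combine_predictions implements all ensemble modes", {
  expect_equal(combine_predictions(2, 4, "mean"), 3)
  expect_equal(combine_predictions(2, 4, "seq_only"), 2)
  expect_equal(combine_predictions(2, 4, "graph_only"), 4)
  expect_equal(combine_predictions(2, 4, "learned_weight", alpha = 0), 3)
  # sigmoid limit: large alpha recovers the sequence branch
  expect_equal(combine_predictions(2, 4, "learned_weight", alpha = 50), 2)
  expect_equal(combine_predictions(c(1, 2), c(3, 6), "mean"), c(2, 4))
  expect_error(combine_predictions(NA, 4, "mean"), "non-finite")
})

test_that("a zero learning rate leaves parameters unchanged", {
  md <- small_model_data(n = 30L)
  tc <- train_config(pretrain_epochs = 1L, lr = 0, batch_size = 8L, seed = 2)
  p0 <- init_generator_params(md$vocab_d, md$vocab_p, md$cfg, seed = 2)
  pt <- pretrain(md, seq_len(30L), NULL, tc, params = p0)
  expect_equal(pt$params, p0, tolerance = 1e-15)
})

test_that("pretraining reduces the training loss and is seed-reproducible", {
  md <- small_model_data(n = 60L)
  tc <- train_config(pretrain_epochs = 5L, lr = 3e-3, batch_size = 16L,
                     seed = 5)
  pt1 <- pretrain(md, 1:48, 49:60, tc)
  pt2 <- pretrain(md, 1:48, 49:60, tc)
  expect_identical(pt1$history, pt2$history)
  expect_lt(utils::tail(pt1$history$train_mse, 1), pt1$history$train_mse[1])
  expect_lte(pt1$best_val_mse, min(pt1$history$val_mse))
  expect_error(pretrain(md, integer(0), NULL, tc), "length")
})

test_that("feature refresh is pure and tracks generator updates", {
  md <- small_model_data(n = 20L)
  p0 <- init_generator_params(md$vocab_d, md$vocab_p, md$cfg, seed = 3)
  f1 <- refresh_node_features(p0, md, 1:10)
  f2 <- refresh_node_features(p0, md, 1:10)
  expect_identical(f1, f2)
  # cached row counts: residues + atoms + 1 central per record
  for (i in 1:10) {
    dc <- md$drug_cache[[md$records$drug_id[i]]]
    pc <- md$prot_cache[[md$records$protein_id[i]]]
    expect_identical(nrow(f1[[as.character(i)]]), pc$n_res + dc$n_atoms + 1L)
  }
  # every transferred row (atoms + residues) is layer normalized
  for (i in 1:10) {
    rows <- f1[[as.character(i)]]
    rows <- rows[-nrow(rows), , drop = FALSE]   # central is an average
    expect_true(all(abs(rowMeans(rows)) < 1e-5))
    v <- apply(rows, 1, function(r) mean((r - mean(r))^2))
    expect_true(all(abs(v - 1) < 1e-3))
  }
  # an optimizer step changes the refreshed features
  tc <- train_config(pretrain_epochs = 1L, lr = 1e-2, batch_size = 8L,
                     seed = 3)
  p1 <- pretrain(md, 1:20, NULL, tc, params = p0)$params
  f3 <- refresh_node_features(p1, md, 1:10)
  expect_false(isTRUE(all.equal(f1, f3)))
})

test_that("the degenerate schedule transfers features exactly once", {
  md <- small_model_data(n = 24L)
  tc <- train_config(pretrain_epochs = 1L, joint_epochs = 3L,
                     update_interval = 3L, batch_size = 8L, seed = 4)
  model <- joint_train(md, 1:20, 21:24, gin_config(n_layers = 2,
                                                   mlp_hidden = 8, dim = 8,
                                                   head_dims = 8), tc)
  expect_identical(model$history$n_refreshes, 1L)
  tc2 <- train_config(pretrain_epochs = 1L, joint_epochs = 4L,
                      update_interval = 2L, batch_size = 8L, seed = 4)
  model2 <- joint_train(md, 1:20, 21:24, gin_config(n_layers = 2,
                                                    mlp_hidden = 8, dim = 8,
                                                    head_dims = 8), tc2)
  expect_identical(model2$history$n_refreshes, 2L)
  expect_error(train_config(joint_epochs = 3L, update_interval = 5L),
               "update_interval")
})

test_that("joint training is deterministic given the seed", {
  md <- small_model_data(n = 40L)
  tc <- train_config(pretrain_epochs = 2L, joint_epochs = 2L,
                     update_interval = 2L, batch_size = 16L, seed = 6)
  gc <- gin_config(n_layers = 2, mlp_hidden = 8, dim = 8, head_dims = 8)
  m1 <- joint_train(md, 1:32, 33:40, gc, tc)
  m2 <- joint_train(md, 1:32, 33:40, gc, tc)
  p1 <- predict_affinity(m1, md)
  p2 <- predict_affinity(m2, md)
  expect_identical(p1, p2)
})

test_that("checkpoints round-trip to identical predictions", {
  md <- small_model_data(n = 30L)
  tc <- train_config(pretrain_epochs = 2L, joint_epochs = 2L,
                     update_interval = 2L, batch_size = 8L, seed = 8)
  gc <- gin_config(n_layers = 2, mlp_hidden = 8, dim = 8, head_dims = 8)
  model <- joint_train(md, 1:24, 25:30, gc, tc)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  model2 <- load_checkpoint(path)
  expect_identical(predict_affinity(model2, md, 1:10),
                   predict_affinity(model, md, 1:10))
  expect_error(load_checkpoint({
    p <- withr::local_tempfile(fileext = ".rds")
    saveRDS(list(1), p); p
  }), "checkpoint")
})

test_that("dropout perturbs training but not evaluation", {
  cfg <- encoder_config(embed_dim = 8L, hidden = 8L, n_heads = 2L,
                        fc_dims = 16L, dropout = 0.5)
  md <- prepare_model_data(small_dataset(30L), cfg)
  p0 <- init_generator_params(md$vocab_d, md$vocab_p, cfg, seed = 2)
  # evaluation-mode predictions ignore dropout entirely
  ns <- asNamespace("hybridDTA")
  pr1 <- ns$seq_predict_all(p0, md, 1:10)
  pr2 <- ns$seq_predict_all(p0, md, 1:10)
  expect_identical(pr1, pr2)
})
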