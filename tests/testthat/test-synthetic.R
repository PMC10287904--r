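test_that("generated SMILES are valid, reproducible, and carry the fragment about half the time", {
  smi <- generate_smiles(60, seed = 2)
  expect_true(all(vapply(smi, is_valid_smiles, logical(1))))
  expect_true(all(vapply(smi, heavy_atom_count, integer(1)) >= 1))
  expect_true(all(vapply(smi, heavy_atom_count, integer(1)) <= 40))
  expect_identical(generate_smiles(60, seed = 2), smi)
  # the grammar keeps nitrogen exclusive to the pharmacophore, so a
  # substring probe is an independent oracle for the planted flag
  expect_identical(unname(grepl("N", smi)),
                   unname(attr(smi, "has_fragment")))
})

test_that("fragment prevalence is binomially consistent with one half", {
  smi <- generate_smiles(500, seed = 8)
  p <- mean(grepl("N", smi))
  expect_gt(p, 0.5 - 3 * sqrt(0.25 / 500))
  expect_lt(p, 0.5 + 3 * sqrt(0.25 / 500))
})

test_that("generated proteins plant the motif and produce valid geometry", {
  g <- generate_protein(40, seed = 3, motif = "HWYKHW", plant = TRUE)
  expect_true(grepl("HWYKHW", g$sequence, fixed = TRUE))
  expect_identical(substr(g$sequence, g$motif_start, g$motif_start + 5L),
                   "HWYKHW")
  expect_equal(g$dist, t(g$dist))
  expect_true(all(diag(g$dist) == 0))
  expect_true(all(g$dist >= 0))
  g2 <- generate_protein(40, seed = 3, plant = FALSE)
  expect_true(is.na(g2$motif_start))
})

test_that("long-range contact density lands at the requested rate", {
  for (dens in c(0.02, 0.05)) {
    g <- generate_protein(60, seed = 5, contact_density = dens)
    cm <- contact_map_from_distances(g$dist, threshold = 8)
    sep <- abs(cm$contacts[, 1] - cm$contacts[, 2])
    n_far_pairs <- sum(abs(outer(1:60, 1:60, "-"))[upper.tri(diag(60))] > 4)
    got <- sum(sep > 4) / n_far_pairs
    expect_gt(got, dens * 0.8)
    expect_lt(got, dens * 1.2)
  }
})

test_that("the planted rule produces the stated affinity arithmetic", {
  spec <- synthetic_spec(n_records = 200, n_drugs = 30, n_proteins = 15,
                         protein_length = c(12L, 20L),
                         motif_effect = 1, fragment_effect = 1,
                         interaction_effect = 2, noise_sd = 0, seed = 5)
  data <- generate_dataset(spec)
  vals <- sort(unique(round(data$records$affinity, 10)))
  expect_true(length(vals) <= 4L)
  expect_true(all(vals %in% c(5, 6, 7, 9)))
  both <- data$truth$has_motif & data$truth$has_fragment
  if (any(both))
    expect_true(all(data$records$affinity[both] == 9))
  # indicators recompute the signal exactly
  expect_equal(5 + 1 * data$truth$has_motif + 1 * data$truth$has_fragment +
                 2 * (data$truth$has_motif & data$truth$has_fragment),
               data$truth$signal)
})

test_that("a linear model on the true indicators explains the signal share of variance", {
  data <- generate_dataset(synthetic_spec(n_records = 1500, seed = 11))
  df <- cbind(data$truth, affinity = data$records$affinity)
  fit <- stats::lm(affinity ~ has_motif * has_fragment, df)
  r2 <- summary(fit)$r.squared
  expected <- stats::var(df$signal) / (stats::var(df$signal) + 0.3^2)
  expect_gt(r2, expected - 0.05)
  expect_lt(r2, expected + 0.05)
})

test_that("dataset generation is deterministic and structurally consistent", {
  spec <- synthetic_spec(n_records = 50, n_drugs = 10, n_proteins = 6,
                         protein_length = c(12L, 20L), seed = 21)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  # motif flags agree with the sequences
  for (pid in names(a$proteins)) {
    p <- a$proteins[[pid]]
    expect_identical(grepl(spec$motif, p$sequence, fixed = TRUE),
                     p$has_motif)
  }
  # no duplicate (drug, protein) pairs
  expect_false(anyDuplicated(paste(a$records$drug_id,
                                   a$records$protein_id)) > 0)
})

test_that("every generated record passes tokenization and hybrid assembly", {
  data <- small_dataset(n = 40L, seed = 3L)
  cfg <- encoder_config(embed_dim = 4, hidden = 3, n_heads = 2, fc_dims = 4)
  md <- prepare_model_data(data, cfg)
  for (i in seq_len(nrow(md$records))) {
    dc <- md$drug_cache[[md$records$drug_id[i]]]
    pc <- md$prot_cache[[md$records$protein_id[i]]]
    expect_identical(md$hybrid[[i]]$n_nodes, pc$n_res + dc$n_atoms + 1L)
    expect_identical(length(dc$atom_pos), dc$n_atoms)
    expect_identical(length(pc$res_pos), pc$n_res)
  }
})
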