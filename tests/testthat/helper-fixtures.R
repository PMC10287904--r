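# Shared fixtures: tiny vocabularies, configurations and datasets built in
# code so every test runs from source with no stored binaries.

tiny_drug_corpus <- function() {
  c("CCO", "CC(=O)NC", "c1ccccc1Cl", "BrCC(F)Cl", "C1CCCC1O")
}

tiny_protein_corpus <- function() {
  c("MKVWACDEFG", "HWYKHWLLST", "GGSAERV")
}

tiny_vocabs <- function() {
  list(d = build_vocab(tiny_drug_corpus(), "drug"),
       p = build_vocab(tiny_protein_corpus(), "protein"))
}

tiny_encoder_cfg <- function() {
  encoder_config(embed_dim = 4L, hidden = 3L, n_heads = 2L, fc_dims = 5L)
}

tiny_generator <- function(seed = 3L) {
  v <- tiny_vocabs()
  cfg <- tiny_encoder_cfg()
  list(cfg = cfg, vocab_d = v$d, vocab_p = v$p,
       params = init_generator_params(v$d, v$p, cfg, seed = seed))
}

# small planted-rule dataset + prepared caches for training tests
small_dataset <- function(n = 120L, seed = 7L) {
  generate_dataset(synthetic_spec(n_records = n, n_drugs = 25L,
                                  n_proteins = 12L,
                                  protein_length = c(15L, 25L),
                                  seed = seed))
}

small_model_data <- function(n = 120L, seed = 7L,
                             cfg = encoder_config(embed_dim = 8L,
                                                  hidden = 8L,
                                                  n_heads = 2L,
                                                  fc_dims = 16L)) {
  prepare_model_data(small_dataset(n, seed), cfg)
}

# random contact map + drug graph pair for structural property tests
random_graph_pair <- function(seed) {
  set.seed(seed)
  n <- sample(3:12, 1)
  d <- matrix(stats::runif(n * n, 2, 20), n, n)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  gp <- contact_map_from_distances(d, threshold = 8)
  smi <- generate_smiles(1, seed = seed)
  gd <- drug_graph_from_smiles(smi[1])
  list(gp = gp, gd = gd, smiles = smi[1])
}

# reachability between node sets in an undirected adjacency matrix
reachable <- function(adj, from, to) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  queue <- from
  seen[from] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    nb <- which(adj[v, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  any(seen[to])
}

# brute-force concordance index (independent O(n^2) oracle)
ci_bruteforce <- function(y, f) {
  num <- 0; den <- 0
  n <- length(y)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (y[i] == y[j]) next
    den <- den + 1
    hi <- if (y[i] > y[j]) c(i, j) else c(j, i)
    if (f[hi[1]] > f[hi[2]]) num <- num + 1
    else if (f[hi[1]] == f[hi[2]]) num <- num + 0.5
  }
  num / den
}

# independently coded rm2 through lm() fits
rm2_lm <- function(y, f) {
  r2 <- summary(stats::lm(y ~ f))$r.squared
  fit0 <- stats::lm(y ~ 0 + f)
  r02 <- 1 - sum(stats::residuals(fit0)^2) / sum((y - mean(y))^2)
  r2 * (1 - sqrt(abs(r2 - r02)))
}
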