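# Synthetic benchmark generator: valid small molecules from a fixed
# fragment grammar, random protein sequences with an optionally planted
# motif, backbone-dominated distance matrices with long-range shortcut
# contacts, and affinities produced by a planted additive-plus-interaction
# rule on a pKd-like scale. The planted indicators are returned so recovery
# tests have ground truth.

# fragment grammar: nitrogen appears only in the pharmacophore fragment, so
# a simple substring probe is an independent presence oracle
.FRAG_START <- c("C", "CC", "CCO", "CCC", "c1ccccc1", "C1CCCCC1", "CC(C)")
.FRAG_MIDDLE <- c("C", "CC", "CCC", "O", "CO", "c1ccccc1", "C1CCCC1",
                  "C(C)", "CC(C)C", "COC")
.FRAG_TERMINAL <- c("", "C", "Cl", "F", "Br", "O", "CC")

#' Synthetic study specification
#'
#' Defaults define the package's reference simulation: a pKd-like affinity
#' (baseline 5) with planted effects for a protein motif, a drug
#' pharmacophore fragment, and their interaction, plus Gaussian noise.
#'
#' @param n_records number of (drug, protein) pairs.
#' @param n_drugs,n_proteins library sizes the pairs are drawn from.
#' @param protein_length integer range of protein lengths.
#' @param motif planted residue substring.
#' @param pharmacophore planted SMILES fragment (amide); the rest of the
#'   grammar contains no nitrogen.
#' @param motif_effect,fragment_effect,interaction_effect additive effect
#'   sizes on the affinity scale.
#' @param noise_sd Gaussian noise standard deviation.
#' @param contact_density fraction of long-range (|i-j| > 4) residue pairs
#'   made contacts at the 8 Angstrom threshold.
#' @param motif_prevalence fraction of proteins carrying the motif.
#' @param baseline affinity baseline (pKd-like).
#' @param seed RNG seed.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_records = 2400L, n_drugs = 100L,
                           n_proteins = 50L, protein_length = c(30L, 60L),
                           motif = "HWYKHW", pharmacophore = "C(=O)N",
                           motif_effect = 0.8, fragment_effect = 0.8,
                           interaction_effect = 1.2, noise_sd = 0.3,
                           contact_density = 0.03, motif_prevalence = 0.5,
                           baseline = 5, seed = 1L) {
  stopifnot(noise_sd >= 0, nchar(motif) < min(protein_length),
            all(is.finite(c(motif_effect, fragment_effect,
                            interaction_effect))))
  structure(list(n_records = as.integer(n_records),
                 n_drugs = as.integer(n_drugs),
                 n_proteins = as.integer(n_proteins),
                 protein_length = as.integer(protein_length),
                 motif = motif, pharmacophore = pharmacophore,
                 motif_effect = motif_effect,
                 fragment_effect = fragment_effect,
                 interaction_effect = interaction_effect,
                 noise_sd = noise_sd, contact_density = contact_density,
                 motif_prevalence = motif_prevalence,
                 baseline = baseline, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate valid SMILES from the fragment grammar
#'
#' Molecules are assembled as start + 1-3 middle fragments + terminal; the
#' pharmacophore fragment is spliced in with probability 0.5. Every output
#' parses and has at most ~40 heavy atoms.
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param pharmacophore fragment inserted with probability 0.5.
#' @return character vector of SMILES with logical attribute
#'   `has_fragment`.
#' @export
generate_smiles <- function(n, seed = 1L, pharmacophore = "C(=O)N") {
  stopifnot(n >= 1)
  set.seed(derive_seed(seed, 41L))
  out <- character(n)
  has <- logical(n)
  for (i in seq_len(n)) {
    mids <- sample(.FRAG_MIDDLE, sample(1:3, 1), replace = TRUE)
    has[i] <- stats::runif(1) < 0.5
    if (has[i]) {
      at <- sample(seq_len(length(mids) + 1L), 1L)
      mids <- append(mids, pharmacophore, after = at - 1L)
    }
    out[i] <- paste0(sample(.FRAG_START, 1), paste(mids, collapse = ""),
                     sample(.FRAG_TERMINAL, 1))
  }
  attr(out, "has_fragment") <- has
  out
}

#' Generate a protein sequence and its distance matrix
#'
#' Residues are i.i.d. over the 20-letter alphabet with the motif spliced
#' at a random position when planted. The distance matrix is dominated by
#' backbone separation (3.8 Angstrom per residue, capped) with long-range
#' shortcuts sampled below the 8 Angstrom contact threshold at the given
#' density.
#'
#' @param length sequence length.
#' @param seed RNG seed.
#' @param motif residue substring to plant.
#' @param plant whether to plant the motif.
#' @param contact_density fraction of |i-j| > 4 pairs made contacts.
#' @return list with `sequence`, `dist` (symmetric, zero diagonal) and
#'   `motif_start` (NA when not planted).
#' @export
generate_protein <- function(length, seed = 1L, motif = "HWYKHW",
                             plant = FALSE, contact_density = 0.03) {
  stopifnot(length >= nchar(motif) + 2L)
  set.seed(derive_seed(seed, 43L))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  res <- sample(aa, length, replace = TRUE)
  motif_start <- NA_integer_
  if (plant) {
    motif_start <- sample.int(length - nchar(motif) + 1L, 1L)
    res[motif_start:(motif_start + nchar(motif) - 1L)] <-
      strsplit(motif, "")[[1]]
  }
  sep <- abs(outer(seq_len(length), seq_len(length), "-"))
  d <- pmin(3.8 * sep, 60)
  # long-range shortcuts: sample pairs with |i-j| > 4 and pull them below
  # the contact threshold
  far <- which(upper.tri(d) & sep > 4)
  n_short <- round(contact_density * length(far))
  if (n_short > 0) {
    pick <- sample(far, n_short)
    d[pick] <- stats::runif(n_short, 4, 7.9)
    dt <- t(d)
    d[lower.tri(d)] <- dt[lower.tri(d)]
  }
  diag(d) <- 0
  list(sequence = paste(res, collapse = ""), dist = d,
       motif_start = motif_start)
}

#' Generate a full synthetic affinity dataset
#'
#' Affinity = baseline + motif_effect * motif + fragment_effect * fragment
#' + interaction_effect * (motif AND fragment) + Normal(0, noise_sd).
#'
#' @param spec a [synthetic_spec()].
#' @return a `dta_dataset`: list with `records` (data frame: drug_id,
#'   smiles, protein_id, sequence, affinity), `proteins` (named list with
#'   sequence + distance matrix + motif flag), `drugs` (named list with
#'   smiles + fragment flag) and `truth` (per-record indicator table).
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  smiles <- generate_smiles(spec$n_drugs, seed = derive_seed(spec$seed, 1L),
                            pharmacophore = spec$pharmacophore)
  has_frag <- attr(smiles, "has_fragment")
  drug_ids <- sprintf("D%03d", seq_len(spec$n_drugs))
  drugs <- stats::setNames(lapply(seq_len(spec$n_drugs), function(i) {
    list(smiles = smiles[i], has_fragment = has_frag[i])
  }), drug_ids)

  set.seed(derive_seed(spec$seed, 2L))
  lens <- sample(spec$protein_length[1]:spec$protein_length[2],
                 spec$n_proteins, replace = TRUE)
  planted <- stats::runif(spec$n_proteins) < spec$motif_prevalence
  prot_ids <- sprintf("P%03d", seq_len(spec$n_proteins))
  proteins <- stats::setNames(lapply(seq_len(spec$n_proteins), function(i) {
    g <- generate_protein(lens[i], seed = derive_seed(spec$seed, 3L, i),
                          motif = spec$motif, plant = planted[i],
                          contact_density = spec$contact_density)
    c(g, list(has_motif = planted[i]))
  }), prot_ids)

  set.seed(derive_seed(spec$seed, 4L))
  n_pairs_max <- spec$n_drugs * spec$n_proteins
  if (spec$n_records > n_pairs_max)
    stop("n_records exceeds the number of distinct (drug, protein) pairs")
  pair_idx <- sample.int(n_pairs_max, spec$n_records)
  di <- ((pair_idx - 1L) %% spec$n_drugs) + 1L
  pj <- ((pair_idx - 1L) %/% spec$n_drugs) + 1L
  m <- as.numeric(planted[pj])
  f <- as.numeric(has_frag[di])
  signal <- spec$baseline + spec$motif_effect * m +
    spec$fragment_effect * f + spec$interaction_effect * m * f
  affinity <- signal + stats::rnorm(spec$n_records, 0, spec$noise_sd)
  records <- data.frame(
    drug_id = drug_ids[di],
    smiles = smiles[di],
    protein_id = prot_ids[pj],
    sequence = vapply(proteins[pj], `[[`, character(1), "sequence"),
    affinity = affinity,
    stringsAsFactors = FALSE, row.names = NULL)
  truth <- data.frame(drug_id = drug_ids[di], protein_id = prot_ids[pj],
                      has_motif = m == 1, has_fragment = f == 1,
                      signal = signal, stringsAsFactors = FALSE)
  structure(list(records = records, drugs = drugs, proteins = proteins,
                 truth = truth, spec = spec),
            class = "dta_dataset")
}

#' @export
print.dta_dataset <- function(x, ...) {
  cat("<dta_dataset>", nrow(x$records), "records |",
      length(x$drugs), "drugs |", length(x$proteins), "proteins\n")
  invisible(x)
}

#' Write a dataset to disk in the standard text formats
#'
#' Writes the affinity table (TSV), one whitespace-delimited square
#' distance matrix per protein, and the ground-truth indicator table.
#'
#' @param data a `dta_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(data, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "distmaps"), showWarnings = FALSE)
  utils::write.table(data$records, file.path(dir, "affinities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (pid in names(data$proteins)) {
    utils::write.table(format(data$proteins[[pid]]$dist, digits = 6),
                       file.path(dir, "distmaps", paste0(pid, ".txt")),
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}
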