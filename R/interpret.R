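# Interpretability: the joint cross-attention weights over the
# concatenated drug and protein positions are mapped back to atoms and
# residues, giving the per-node contribution of each amino acid and atom
# to the predicted affinity.

#' Attention map over residues and atoms
#'
#' Runs the feature generator on one record, takes the joint
#' cross-attention weights (averaged over heads), maps token positions
#' back to residue/atom indices through the node index maps (dropping
#' classification, bond and branch positions), and renormalizes so the
#' combined protein + drug mass is 1. Deterministic for a fixed model.
#'
#' @param model a `dta_model`.
#' @param smiles drug SMILES.
#' @param sequence protein sequence.
#' @return an `attention_map`: list with `protein_weights` (length
#'   n_residues), `drug_weights` (length n_atoms), and `head_weights`
#'   (raw per-head position weights before aggregation, drug positions
#'   first).
#' @export
attention_map <- function(model, smiles, sequence) {
  stopifnot(inherits(model, "dta_model"))
  cfg <- model$encoder_cfg
  tok_d <- tokenize_drug(smiles, model$vocab_d, max_len = cfg$max_drug_len)
  tok_p <- tokenize_protein(sequence, model$vocab_p,
                            max_len = cfg$max_protein_len)
  h_d <- encode(tok_d, cfg, model$gen_params)
  h_p <- encode(tok_p, cfg, model$gen_params)
  cp <- cross_pool(h_d, h_p, cfg, model$gen_params)
  w <- rowMeans(cp$weights)              # average heads
  m_d <- nrow(h_d)
  pos_d <- as.integer(names(tok_d$node_index_map))
  pos_p <- as.integer(names(tok_p$node_index_map))
  wd <- w[pos_d]
  wp <- w[m_d + pos_p]
  total <- sum(wd) + sum(wp)
  if (total <= 0) stop("degenerate attention mass")
  structure(list(protein_weights = wp / total,
                 drug_weights = wd / total,
                 head_weights = cp$weights,
                 n_drug_positions = m_d),
            class = "attention_map")
}

#' Top-k nodes by attention weight
#'
#' @param map an `attention_map`.
#' @param k number of nodes.
#' @param side `"protein"` or `"drug"`.
#' @return 1-based indices sorted by descending weight, ties broken by
#'   ascending index; length `min(k, n)`.
#' @export
top_k_nodes <- function(map, k, side = c("protein", "drug")) {
  side <- match.arg(side)
  stopifnot(k >= 1)
  w <- if (side == "protein") map$protein_weights else map$drug_weights
  ord <- order(-w, seq_along(w))
  ord[seq_len(min(k, length(w)))]
}

#' Write an attention map as two-column text files
#'
#' One `(index, weight)` file per side.
#'
#' @param map an `attention_map`.
#' @param prefix output path prefix; writes `<prefix>_protein.txt` and
#'   `<prefix>_drug.txt`.
#' @export
write_attention_map <- function(map, prefix) {
  for (side in c("protein", "drug")) {
    w <- map[[paste0(side, "_weights")]]
    utils::write.table(data.frame(index = seq_along(w), weight = w),
                       paste0(prefix, "_", side, ".txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(prefix)
}
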