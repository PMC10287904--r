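# Sequence-based feature generator: two independent bidirectional recurrent
# encoders (drug SMILES tokens, protein residues), per-molecule multi-head
# linear attention pooling, a joint cross-attention over the concatenated
# positions, and a fully connected head that predicts affinity from
# concat(O_d, O_p, O_con). The same encoder outputs are gathered, row-wise
# layer normalized, and handed to the hybrid GNN as node features.
#
# Everything is written forward/backward by hand over flat parameter lists;
# the test suite checks the analytic gradients against finite differences.

#' Encoder configuration
#'
#' @param embed_dim token embedding width.
#' @param hidden recurrent state width per direction; the per-token feature
#'   width is `2 * hidden` and is shared by the drug and protein encoders
#'   (required so the two classification-token embeddings can be averaged
#'   into the central-node feature).
#' @param n_heads number of linear-attention heads.
#' @param d_k positive score normalizer; default `sqrt(2 * hidden)`.
#' @param dropout dropout rate in `[0, 1)` applied to the pooled feature
#'   vector during training.
#' @param fc_dims hidden widths of the prediction head.
#' @param max_drug_len,max_protein_len token truncation lengths (excluding
#'   the classification token).
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(embed_dim = 32L, hidden = 32L, n_heads = 4L,
                           d_k = NULL, dropout = 0, fc_dims = c(64L, 32L),
                           max_drug_len = 100L, max_protein_len = 1000L) {
  stopifnot(embed_dim >= 1, hidden >= 1, n_heads >= 1,
            dropout >= 0, dropout < 1)
  d_k <- d_k %||% sqrt(2 * hidden)
  stopifnot(d_k > 0)
  structure(list(embed_dim = as.integer(embed_dim),
                 hidden = as.integer(hidden),
                 width = 2L * as.integer(hidden),
                 n_heads = as.integer(n_heads), d_k = d_k,
                 dropout = dropout, fc_dims = as.integer(fc_dims),
                 max_drug_len = as.integer(max_drug_len),
                 max_protein_len = as.integer(max_protein_len)),
            class = "encoder_config")
}

#' Initialize feature-generator parameters
#'
#' @param vocab_d,vocab_p drug and protein vocabularies.
#' @param cfg an [encoder_config()].
#' @param seed RNG seed.
#' @return flat named list of parameter matrices.
#' @export
init_generator_params <- function(vocab_d, vocab_p, cfg, seed = 1L) {
  set.seed(derive_seed(seed, 11L))
  D <- cfg$width; K <- cfg$n_heads; de <- cfg$embed_dim; H <- cfg$hidden
  p <- list()
  for (k in c("d", "p")) {
    V <- length(if (k == "d") vocab_d$token_to_id else vocab_p$token_to_id)
    p[[paste0(k, "_emb")]] <- nn_init_mat(V, de, scale = 0.1)
    for (dir in c("f", "b")) {
      p[[paste0(k, "_W", dir)]] <- nn_init_mat(de, H)
      p[[paste0(k, "_U", dir)]] <- nn_init_mat(H, H)
      p[[paste0(k, "_b", dir)]] <- nn_zeros(1L, H)
    }
    p[[paste0(k, "_att_w")]] <- nn_init_mat(D, K)
    p[[paste0(k, "_att_mix")]] <- nn_init_mat(K * D, D)
    p[[paste0(k, "_att_mixb")]] <- nn_zeros(1L, D)
  }
  p[["con_att_w"]] <- nn_init_mat(D, K)
  p[["con_att_mix"]] <- nn_init_mat(K * D, D)
  p[["con_att_mixb"]] <- nn_zeros(1L, D)
  p <- c(p, nn_init_mlp("seq_fc", c(3L * D, cfg$fc_dims, 1L)))
  p
}

# --- bidirectional recurrent encoder ---------------------------------------

# ids: B x L matrix of 0-based token ids (pad id on the tail); lengths
# include the classification token. Returns forward states and
# reversed-time backward states as B x H x L arrays plus caches for BPTT.
#' @noRd
rnn_forward <- function(ids, lengths, params, prefix, cfg) {
  B <- nrow(ids); L <- ncol(ids); H <- cfg$hidden
  emb <- params[[paste0(prefix, "_emb")]]
  ids_rev <- ids
  for (b in seq_len(B)) ids_rev[b, seq_len(lengths[b])] <-
    ids[b, rev(seq_len(lengths[b]))]
  run <- function(idm, dir) {
    W <- params[[paste0(prefix, "_W", dir)]]
    U <- params[[paste0(prefix, "_U", dir)]]
    bb <- params[[paste0(prefix, "_b", dir)]]
    Hs <- array(0, c(B, H, L))
    hprev <- matrix(0, B, H)
    for (t in seq_len(L)) {
      E <- emb[idm[, t] + 1L, , drop = FALSE]
      hprev <- tanh(nn_addb(E %*% W + hprev %*% U, bb))
      Hs[, , t] <- hprev
    }
    Hs
  }
  list(HF = run(ids, "f"), HBr = run(ids_rev, "b"),
       ids = ids, ids_rev = ids_rev, lengths = lengths)
}

# per-record token-embedding matrices (length_b x 2H), rows in token order
#' @noRd
rnn_gather <- function(rc, cfg) {
  B <- length(rc$lengths); H <- cfg$hidden
  lapply(seq_len(B), function(b) {
    len <- rc$lengths[b]
    fwd <- matrix(rc$HF[b, , seq_len(len)], nrow = H)
    bwd <- matrix(rc$HBr[b, , rev(seq_len(len))], nrow = H)
    cbind(t(fwd), t(bwd))
  })
}

# BPTT given per-record gradients dH (list of length_b x 2H matrices)
#' @noRd
rnn_backward <- function(dH, rc, params, prefix, cfg, grads) {
  B <- length(rc$lengths); H <- cfg$hidden; L <- dim(rc$HF)[3]
  emb <- params[[paste0(prefix, "_emb")]]
  dHF <- array(0, c(B, H, L)); dHBr <- array(0, c(B, H, L))
  for (b in seq_len(B)) {
    len <- rc$lengths[b]
    dHF[b, , seq_len(len)] <- t(dH[[b]][, seq_len(H), drop = FALSE])
    dHBr[b, , seq_len(len)] <-
      t(dH[[b]][rev(seq_len(len)), H + seq_len(H), drop = FALSE])
  }
  demb <- matrix(0, nrow(emb), ncol(emb))
  run_bwd <- function(idm, Hs, dHs, dir) {
    W <- params[[paste0(prefix, "_W", dir)]]
    U <- params[[paste0(prefix, "_U", dir)]]
    dW <- matrix(0, nrow(W), ncol(W)); dU <- matrix(0, H, H)
    db <- matrix(0, 1L, H)
    g <- matrix(0, B, H)
    for (t in rev(seq_len(L))) {
      ht <- matrix(Hs[, , t], B, H)
      dA <- (matrix(dHs[, , t], B, H) + g) * (1 - ht * ht)
      E <- emb[idm[, t] + 1L, , drop = FALSE]
      dW <- dW + crossprod(E, dA)
      hp <- if (t > 1L) matrix(Hs[, , t - 1L], B, H) else matrix(0, B, H)
      dU <- dU + crossprod(hp, dA)
      db <- db + colSums(dA)
      dE <- dA %*% t(W)
      agg <- rowsum(dE, group = idm[, t] + 1L)
      ridx <- as.integer(rownames(agg))
      demb[ridx, ] <<- demb[ridx, , drop = FALSE] + agg
      g <- dA %*% t(U)
    }
    grads[[paste0(prefix, "_W", dir)]] <<-
      (grads[[paste0(prefix, "_W", dir)]] %||% 0) + dW
    grads[[paste0(prefix, "_U", dir)]] <<-
      (grads[[paste0(prefix, "_U", dir)]] %||% 0) + dU
    grads[[paste0(prefix, "_b", dir)]] <<-
      (grads[[paste0(prefix, "_b", dir)]] %||% 0) + db
  }
  run_bwd(rc$ids, rc$HF, dHF, "f")
  run_bwd(rc$ids_rev, rc$HBr, dHBr, "b")
  grads[[paste0(prefix, "_emb")]] <-
    (grads[[paste0(prefix, "_emb")]] %||% 0) + demb
  grads
}

# --- multi-head linear attention -------------------------------------------

# H_list: per-record position x width matrices. Per head k the scalar score
# of position i is (h_i . w_k) / d_k, softmaxed over positions; the pooled
# vector is the weight-averaged embedding, heads concatenated.
#' @noRd
attn_forward <- function(H_list, w, d_k) {
  K <- ncol(w); D <- nrow(w)
  B <- length(H_list)
  Opool <- matrix(0, B, K * D)
  alphas <- vector("list", B)
  for (b in seq_len(B)) {
    Hb <- H_list[[b]]
    S <- (Hb %*% w) / d_k
    al <- nn_softmax_cols(S)
    P <- crossprod(Hb, al)            # D x K
    Opool[b, ] <- as.vector(P)
    alphas[[b]] <- al
  }
  list(Opool = Opool, alphas = alphas)
}

# backward: dOpool (B x K*D) -> per-record dH list + dw accumulation
#' @noRd
attn_backward <- function(dOpool, H_list, alphas, w, d_k, grads, wname) {
  K <- ncol(w); D <- nrow(w)
  B <- length(H_list)
  dw <- matrix(0, D, K)
  dH <- vector("list", B)
  for (b in seq_len(B)) {
    Hb <- H_list[[b]]
    al <- alphas[[b]]
    dP <- matrix(dOpool[b, ], D, K)
    dal <- Hb %*% dP
    dHb <- al %*% t(dP)
    ds <- al * (dal - rep(colSums(al * dal), each = nrow(al)))
    dw <- dw + crossprod(Hb, ds) / d_k
    dHb <- dHb + (ds %*% t(w)) / d_k
    dH[[b]] <- dHb
  }
  grads[[wname]] <- (grads[[wname]] %||% 0) + dw
  list(dH = dH, grads = grads)
}

# --- full generator forward/backward over a prepared batch -----------------

# batch: list(d_ids, d_len, p_ids, p_len) with 0-based id matrices.
#' @noRd
gen_forward <- function(batch, params, cfg, dropout_mask = NULL) {
  rc_d <- rnn_forward(batch$d_ids, batch$d_len, params, "d", cfg)
  rc_p <- rnn_forward(batch$p_ids, batch$p_len, params, "p", cfg)
  Hd <- rnn_gather(rc_d, cfg)
  Hp <- rnn_gather(rc_p, cfg)
  Hcon <- mapply(rbind, Hd, Hp, SIMPLIFY = FALSE)
  at_d <- attn_forward(Hd, params$d_att_w, cfg$d_k)
  at_p <- attn_forward(Hp, params$p_att_w, cfg$d_k)
  at_c <- attn_forward(Hcon, params$con_att_w, cfg$d_k)
  Od <- nn_addb(at_d$Opool %*% params$d_att_mix, params$d_att_mixb)
  Op <- nn_addb(at_p$Opool %*% params$p_att_mix, params$p_att_mixb)
  Oc <- nn_addb(at_c$Opool %*% params$con_att_mix, params$con_att_mixb)
  Z <- cbind(Od, Op, Oc)
  if (!is.null(dropout_mask)) Z <- Z * dropout_mask
  n_fc <- length(cfg$fc_dims) + 1L
  head <- nn_mlp_forward(Z, params, "seq_fc", n_fc)
  list(pred = as.vector(head$out),
       rc_d = rc_d, rc_p = rc_p, Hd = Hd, Hp = Hp, Hcon = Hcon,
       at_d = at_d, at_p = at_p, at_c = at_c,
       Opool_d = at_d$Opool, Opool_p = at_p$Opool, Opool_c = at_c$Opool,
       Z = Z, head = head, dropout_mask = dropout_mask)
}

#' @noRd
gen_backward <- function(dpred, fw, params, cfg) {
  grads <- list()
  n_fc <- length(cfg$fc_dims) + 1L
  hb <- nn_mlp_backward(matrix(dpred, ncol = 1L), fw$head, params,
                        "seq_fc", n_fc, grads)
  grads <- hb$grads
  dZ <- hb$dx
  if (!is.null(fw$dropout_mask)) dZ <- dZ * fw$dropout_mask
  D <- cfg$width
  dOd <- dZ[, seq_len(D), drop = FALSE]
  dOp <- dZ[, D + seq_len(D), drop = FALSE]
  dOc <- dZ[, 2L * D + seq_len(D), drop = FALSE]
  bk_mix <- function(dO, Opool, mixname, bname) {
    grads[[mixname]] <<- (grads[[mixname]] %||% 0) + crossprod(Opool, dO)
    grads[[bname]] <<- (grads[[bname]] %||% 0) + matrix(colSums(dO), 1L)
    dO %*% t(params[[mixname]])
  }
  dPo_d <- bk_mix(dOd, fw$Opool_d, "d_att_mix", "d_att_mixb")
  dPo_p <- bk_mix(dOp, fw$Opool_p, "p_att_mix", "p_att_mixb")
  dPo_c <- bk_mix(dOc, fw$Opool_c, "con_att_mix", "con_att_mixb")
  ab_d <- attn_backward(dPo_d, fw$Hd, fw$at_d$alphas, params$d_att_w,
                        cfg$d_k, grads, "d_att_w")
  grads <- ab_d$grads
  ab_p <- attn_backward(dPo_p, fw$Hp, fw$at_p$alphas, params$p_att_w,
                        cfg$d_k, grads, "p_att_w")
  grads <- ab_p$grads
  ab_c <- attn_backward(dPo_c, fw$Hcon, fw$at_c$alphas, params$con_att_w,
                        cfg$d_k, grads, "con_att_w")
  grads <- ab_c$grads
  # split the cross-attention gradients back to the two molecules
  dHd <- ab_d$dH
  dHp <- ab_p$dH
  for (b in seq_along(dHd)) {
    nd <- nrow(dHd[[b]])
    dHd[[b]] <- dHd[[b]] + ab_c$dH[[b]][seq_len(nd), , drop = FALSE]
    dHp[[b]] <- dHp[[b]] +
      ab_c$dH[[b]][nd + seq_len(nrow(dHp[[b]])), , drop = FALSE]
  }
  grads <- rnn_backward(dHd, fw$rc_d, params, "d", cfg, grads)
  grads <- rnn_backward(dHp, fw$rc_p, params, "p", cfg, grads)
  grads
}

# --- exported single-example operations ------------------------------------

#' Encode a tokenized sequence into per-token embeddings
#'
#' Runs the kind-matched bidirectional recurrent encoder; row i of the
#' output corresponds to token i (row 1 is the classification token).
#'
#' @param tokseq a `dta_tokseq`.
#' @param cfg an [encoder_config()].
#' @param params generator parameters from [init_generator_params()].
#' @return a `token_embeddings` matrix (tokens x `cfg$width`) with
#'   attributes `kind` and `tokseq`.
#' @export
encode <- function(tokseq, cfg, params) {
  stopifnot(inherits(tokseq, "dta_tokseq"))
  if (length(tokseq$ids) < 2L) stop("sequence too short to encode")
  prefix <- if (tokseq$kind == "drug") "d" else "p"
  V <- nrow(params[[paste0(prefix, "_emb")]])
  if (any(tokseq$ids < 0L | tokseq$ids >= V))
    stop("token id out of vocabulary range")
  ids <- matrix(tokseq$ids, nrow = 1L)
  rc <- rnn_forward(ids, length(tokseq$ids), params, prefix, cfg)
  h <- rnn_gather(rc, cfg)[[1]]
  structure(h, kind = tokseq$kind, tokseq = tokseq,
            class = c("token_embeddings", "matrix", "array"))
}

#' Multi-head linear attention pooling over one sequence
#'
#' Per head, position i receives the scalar score `(h_i . w) / d_k`; the
#' weights are the softmax of the scores over positions and the pooled
#' vector is the weight-averaged embedding, heads concatenated.
#'
#' @param h a `token_embeddings` matrix (or plain positions x width matrix).
#' @param cfg an [encoder_config()].
#' @param params generator parameters.
#' @param kind which attention parameters to use; inferred from `h` when
#'   it carries a kind attribute.
#' @return list with `pooled` (length `n_heads * width` concatenation),
#'   `mixed` (length `width`, after the linear head mix) and `weights`
#'   (positions x heads, each column summing to 1).
#' @export
attention_pool <- function(h, cfg, params, kind = NULL) {
  kind <- kind %||% attr(h, "kind")
  stopifnot(kind %in% c("drug", "protein"))
  if (is.null(dim(h)) || nrow(h) == 0L) stop("empty input to attention_pool")
  prefix <- if (kind == "drug") "d" else "p"
  w <- params[[paste0(prefix, "_att_w")]]
  at <- attn_forward(list(unclass(h)), w, cfg$d_k)
  mixed <- nn_addb(at$Opool %*% params[[paste0(prefix, "_att_mix")]],
                   params[[paste0(prefix, "_att_mixb")]])
  list(pooled = as.vector(at$Opool), mixed = as.vector(mixed),
       weights = at$alphas[[1]])
}

#' Joint cross-attention over drug and protein positions
#'
#' The two embedding matrices are concatenated along the position axis
#' (length `m_d + m_p`) and pooled with the joint attention heads; the
#' per-position weights over both molecules are the model's
#' interpretability surface.
#'
#' @param h_d,h_p drug / protein `token_embeddings`.
#' @param cfg an [encoder_config()].
#' @param params generator parameters.
#' @return as [attention_pool()]; `weights` has `m_d + m_p` rows (drug
#'   positions first).
#' @export
cross_pool <- function(h_d, h_p, cfg, params) {
  if (ncol(h_d) != ncol(h_p))
    stop("drug and protein embedding widths differ")
  hcon <- rbind(unclass(h_d), unclass(h_p))
  at <- attn_forward(list(hcon), params$con_att_w, cfg$d_k)
  mixed <- nn_addb(at$Opool %*% params$con_att_mix, params$con_att_mixb)
  list(pooled = as.vector(at$Opool), mixed = as.vector(mixed),
       weights = at$alphas[[1]], n_drug_positions = nrow(h_d))
}

#' Sequence-level affinity prediction from pooled features
#'
#' Fully connected head over `concat(O_d, O_p, O_con)`.
#'
#' @param O_d,O_p,O_con pooled (mixed) feature vectors of width
#'   `cfg$width`, or matrices with one example per row.
#' @param cfg an [encoder_config()].
#' @param params generator parameters.
#' @return numeric vector of predictions.
#' @export
sequence_predict <- function(O_d, O_p, O_con, cfg, params) {
  as_row <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else x
  Z <- cbind(as_row(O_d), as_row(O_p), as_row(O_con))
  if (!all(is.finite(Z))) stop("non-finite pooled input")
  n_fc <- length(cfg$fc_dims) + 1L
  as.vector(nn_mlp_forward(Z, params, "seq_fc", n_fc)$out)
}

#' Gather encoder outputs into hybrid-graph node features
#'
#' Rows are selected through the token-to-node index maps (special and
#' bond tokens never contribute), each row is layer normalized, and the
#' central-node feature is the mean of the two normalized
#' classification-token embeddings.
#'
#' @param h_d,h_p drug / protein `token_embeddings`.
#' @param tok_d,tok_p the matching `dta_tokseq` objects (for the maps);
#'   defaults to the maps attached to the embeddings.
#' @param normalize apply per-row layer normalization (default TRUE).
#' @return a `node_feature_set`: list with `protein_features`
#'   (n_residues x width), `drug_features` (n_atoms x width) and
#'   `central_feature` (width).
#' @export
extract_node_features <- function(h_d, h_p, tok_d = attr(h_d, "tokseq"),
                                  tok_p = attr(h_p, "tokseq"),
                                  normalize = TRUE) {
  pos_d <- as.integer(names(tok_d$node_index_map))
  pos_p <- as.integer(names(tok_p$node_index_map))
  if (max(pos_d) > nrow(h_d) || max(pos_p) > nrow(h_p))
    stop("node index map exceeds embedding length")
  maybe_ln <- function(m) {
    if (normalize) nn_layernorm_rows(m)$y else m
  }
  fd <- maybe_ln(unclass(h_d)[pos_d, , drop = FALSE])
  fp <- maybe_ln(unclass(h_p)[pos_p, , drop = FALSE])
  cls_d <- if (normalize) nn_layernorm_vec(unclass(h_d)[1L, ]) else
    unclass(h_d)[1L, ]
  cls_p <- if (normalize) nn_layernorm_vec(unclass(h_p)[1L, ]) else
    unclass(h_p)[1L, ]
  structure(list(protein_features = fp, drug_features = fd,
                 central_feature = (cls_d + cls_p) / 2),
            class = "node_feature_set")
}
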