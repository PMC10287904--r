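# Three-phase training: (1) pre-train the sequence-based feature generator
# on affinity MSE; (2) transfer layer-normalized node features to the
# hybrid GNN, refreshed every update_interval epochs; (3) jointly optimize
# both branches on the MSE of the ensembled prediction. The GNN consumes
# the cached (detached) features between refreshes, which is what keeps
# the two co-trained networks from chasing each other's drifting features.

#' Training configuration
#'
#' @param pretrain_epochs,joint_epochs epoch budgets for the two phases.
#' @param update_interval epochs between node-feature refreshes during
#'   joint training (must not exceed `joint_epochs`).
#' @param lr Adam learning rate.
#' @param weight_decay L2 penalty added to gradients.
#' @param batch_size minibatch size.
#' @param seed RNG seed controlling init, shuffling and dropout.
#' @param ensemble_mode `"learned_weight"` (sigmoid-gated convex
#'   combination, gate trained jointly), `"mean"`, `"seq_only"` or
#'   `"graph_only"`.
#' @param patience early-stopping patience (epochs without validation
#'   improvement).
#' @param freeze_generator stop generator updates during joint training.
#' @param aux_branch_weight weight of the auxiliary per-branch MSE losses
#'   added to the ensemble loss during joint training. The default 0
#'   optimizes the ensemble alone; a positive value anchors each branch to
#'   the labels, preventing the branches from drifting to mutually
#'   cancelling biases.
#' @return a `train_config` list.
#' @export
train_config <- function(pretrain_epochs = 30L, joint_epochs = 15L,
                         update_interval = 5L, lr = 2e-3, weight_decay = 0,
                         batch_size = 128L, seed = 1L,
                         ensemble_mode = c("learned_weight", "mean",
                                           "seq_only", "graph_only"),
                         patience = 10L, freeze_generator = FALSE,
                         aux_branch_weight = 0) {
  ensemble_mode <- match.arg(ensemble_mode)
  stopifnot(pretrain_epochs >= 1, joint_epochs >= 0, update_interval >= 1,
            lr >= 0, batch_size >= 1, patience >= 1)
  if (joint_epochs >= 1 && update_interval > joint_epochs)
    stop("update_interval must not exceed joint_epochs")
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 joint_epochs = as.integer(joint_epochs),
                 update_interval = as.integer(update_interval),
                 lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), ensemble_mode = ensemble_mode,
                 patience = as.integer(patience),
                 freeze_generator = isTRUE(freeze_generator),
                 aux_branch_weight = aux_branch_weight),
            class = "train_config")
}

# --- dataset preparation ----------------------------------------------------

#' Prepare a dataset for training: vocabularies, token and graph caches
#'
#' Tokenizes every unique drug and protein once, builds the drug bond
#' graphs and protein contact maps, assembles per-record hybrid edge
#' lists, and indexes records into the caches. Truncation is applied
#' consistently to tokens, node maps and graphs.
#'
#' @param data a `dta_dataset`.
#' @param cfg an [encoder_config()].
#' @param vocab_d,vocab_p optional prebuilt vocabularies (built from the
#'   dataset when NULL).
#' @param contact_threshold Angstrom threshold for contact maps built from
#'   distance matrices.
#' @return a `model_data` list used by the training functions.
#' @export
prepare_model_data <- function(data, cfg, vocab_d = NULL, vocab_p = NULL,
                               contact_threshold = 8) {
  stopifnot(inherits(data, "dta_dataset"))
  rec <- data$records
  drug_ids <- unique(rec$drug_id)
  prot_ids <- unique(rec$protein_id)
  smiles_of <- vapply(data$drugs[drug_ids], `[[`, character(1), "smiles")
  seq_of <- vapply(data$proteins[prot_ids], `[[`, character(1), "sequence")
  vocab_d <- vocab_d %||% build_vocab(smiles_of, "drug")
  vocab_p <- vocab_p %||% build_vocab(seq_of, "protein")

  drug_cache <- lapply(drug_ids, function(d) {
    tok <- tokenize_drug(smiles_of[[d]], vocab_d,
                         max_len = cfg$max_drug_len, validate = FALSE)
    g <- drug_graph_from_smiles(smiles_of[[d]])
    n_tok_atoms <- length(tok$node_index_map)
    if (n_tok_atoms < g$n_atoms) {   # truncated: drop trailing atoms
      keep <- g$edges[, 1] < n_tok_atoms & g$edges[, 2] < n_tok_atoms
      g$edges <- g$edges[keep, , drop = FALSE]
      g$n_atoms <- n_tok_atoms
    }
    list(ids = tok$ids, atom_pos = as.integer(names(tok$node_index_map)),
         n_atoms = g$n_atoms, edges = g$edges)
  })
  names(drug_cache) <- drug_ids

  prot_cache <- lapply(prot_ids, function(p) {
    tok <- tokenize_protein(seq_of[[p]], vocab_p,
                            max_len = cfg$max_protein_len)
    n_res <- length(tok$node_index_map)
    dist <- data$proteins[[p]]$dist
    cm <- if (!is.null(dist)) {
      contact_map_from_distances(dist, threshold = contact_threshold)
    } else {
      # no structure supplied: fall back to the backbone chain graph
      structure(list(n_residues = nchar(seq_of[[p]]),
                     contacts = cbind(0:(nchar(seq_of[[p]]) - 2L),
                                      1:(nchar(seq_of[[p]]) - 1L)),
                     threshold = NA_real_), class = "contact_map")
    }
    if (n_res < cm$n_residues) {
      keep <- cm$contacts[, 1] < n_res & cm$contacts[, 2] < n_res
      cm$contacts <- cm$contacts[keep, , drop = FALSE]
      cm$n_residues <- n_res
    }
    list(ids = tok$ids, res_pos = as.integer(names(tok$node_index_map)),
         n_res = cm$n_residues, contacts = cm$contacts)
  })
  names(prot_cache) <- prot_ids

  hybrid <- lapply(seq_len(nrow(rec)), function(i) {
    dc <- drug_cache[[rec$drug_id[i]]]
    pc <- prot_cache[[rec$protein_id[i]]]
    gp <- structure(list(n_residues = pc$n_res, contacts = pc$contacts,
                         threshold = NA_real_), class = "contact_map")
    gd <- structure(list(n_atoms = dc$n_atoms, edges = dc$edges),
                    class = "drug_graph")
    hg <- build_hybrid_graph(gp, gd)
    list(edges = hg$edges, n_nodes = hg$n_protein + hg$n_drug + 1L)
  })

  structure(list(records = rec, drug_cache = drug_cache,
                 prot_cache = prot_cache, hybrid = hybrid,
                 vocab_d = vocab_d, vocab_p = vocab_p, cfg = cfg,
                 contact_threshold = contact_threshold),
            class = "model_data")
}

# pad per-record id vectors into a B x Lmax matrix of 0-based ids
#' @noRd
pad_ids <- function(id_list, pad_id) {
  L <- max(lengths(id_list))
  B <- length(id_list)
  m <- matrix(pad_id, B, L)
  for (b in seq_len(B)) m[b, seq_along(id_list[[b]])] <- id_list[[b]]
  m
}

#' @noRd
make_seq_batch <- function(md, idx) {
  did <- md$records$drug_id[idx]
  pid <- md$records$protein_id[idx]
  d_ids <- lapply(md$drug_cache[did], `[[`, "ids")
  p_ids <- lapply(md$prot_cache[pid], `[[`, "ids")
  pad_d <- md$vocab_d$token_to_id[[PAD_TOKEN]]
  pad_p <- md$vocab_p$token_to_id[[PAD_TOKEN]]
  list(d_ids = pad_ids(d_ids, pad_d), d_len = lengths(d_ids),
       p_ids = pad_ids(p_ids, pad_p), p_len = lengths(p_ids),
       y = md$records$affinity[idx], idx = idx)
}

# node features for every record in idx, computed from generator params in
# evaluation mode; returns list of stacked (n_res + n_atoms + 1) x D
# matrices, protein rows first, drug rows second, central last
#' @noRd
compute_node_features <- function(params, md, idx, chunk = 128L) {
  out <- vector("list", length(idx))
  for (start in seq(1L, length(idx), by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, length(idx))]
    batch <- make_seq_batch(md, sub)
    fw <- gen_forward(batch, params, md$cfg)
    for (b in seq_along(sub)) {
      i <- sub[b]
      dc <- md$drug_cache[[md$records$drug_id[i]]]
      pc <- md$prot_cache[[md$records$protein_id[i]]]
      fp <- nn_layernorm_rows(fw$Hp[[b]][pc$res_pos, , drop = FALSE])$y
      fd <- nn_layernorm_rows(fw$Hd[[b]][dc$atom_pos, , drop = FALSE])$y
      central <- (nn_layernorm_vec(fw$Hd[[b]][1L, ]) +
                  nn_layernorm_vec(fw$Hp[[b]][1L, ])) / 2
      out[[start + b - 1L]] <- rbind(fp, fd, central)
    }
  }
  names(out) <- as.character(idx)
  out
}

#' Recompute and cache node features for a set of records
#'
#' Pure function of the generator parameters and the records: two calls
#' with unchanged parameters return identical caches. Every cached row
#' satisfies the layer-normalization invariant (near-zero mean, near-unit
#' variance), guarding against feature drift between refreshes.
#'
#' @param params generator parameters.
#' @param md a `model_data`.
#' @param idx record indices (default: all).
#' @return named list (by record index) of stacked node-feature matrices.
#' @export
refresh_node_features <- function(params, md, idx = seq_len(nrow(md$records))) {
  compute_node_features(params, md, idx)
}

# assemble the batched graph inputs for records idx from a feature cache
#' @noRd
make_graph_batch <- function(md, idx, feat_cache) {
  B <- length(idx)
  n_nodes <- vapply(md$hybrid[idx], `[[`, integer(1), "n_nodes")
  offset <- c(0L, cumsum(n_nodes))[seq_len(B)]
  X <- do.call(rbind, feat_cache[as.character(idx)])
  edges <- do.call(rbind, lapply(seq_len(B), function(b)
    md$hybrid[[idx[b]]]$edges + offset[b]))
  A <- hybrid_adjacency_sparse(edges, sum(n_nodes))
  graph_id <- rep(seq_len(B), n_nodes)
  central_rows <- offset + n_nodes      # central node is last in each block
  list(A = A, X = X, graph_id = graph_id, central_rows = central_rows)
}

#' Combine the two branch predictions
#'
#' @param seq_pred,graph_pred numeric predictions.
#' @param mode ensemble mode (see [train_config()]).
#' @param alpha gate parameter for `"learned_weight"`; the sequence branch
#'   weight is `sigmoid(alpha)`.
#' @return numeric vector of final predictions.
#' @export
combine_predictions <- function(seq_pred, graph_pred,
                                mode = c("mean", "learned_weight",
                                         "seq_only", "graph_only"),
                                alpha = 0) {
  mode <- match.arg(mode)
  if (!all(is.finite(seq_pred)) || !all(is.finite(graph_pred)))
    stop("non-finite branch predictions")
  w <- switch(mode,
              mean = 0.5,
              learned_weight = 1 / (1 + exp(-alpha)),
              seq_only = 1,
              graph_only = 0)
  w * seq_pred + (1 - w) * graph_pred
}

# evaluation-mode sequence predictions for a set of records
#' @noRd
seq_predict_all <- function(params, md, idx, chunk = 256L) {
  preds <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, length(idx))]
    fw <- gen_forward(make_seq_batch(md, sub), params, md$cfg)
    preds[start:(start + length(sub) - 1L)] <- fw$pred
  }
  preds
}

#' @noRd
graph_predict_all <- function(gnn_params, gin_cfg, md, idx, feat_cache,
                              chunk = 256L) {
  preds <- numeric(length(idx))
  for (start in seq(1L, length(idx), by = chunk)) {
    sub <- idx[start:min(start + chunk - 1L, length(idx))]
    gb <- make_graph_batch(md, sub, feat_cache)
    fw <- gnn_forward_batch(gb$A, gb$X, gb$graph_id, gb$central_rows,
                            gin_cfg, gnn_params)
    preds[start:(start + length(sub) - 1L)] <- fw$pred
  }
  preds
}

#' Pre-train the sequence-based feature generator
#'
#' Minimizes the MSE of the sequence-branch prediction with Adam; tracks
#' per-epoch training and validation MSE and returns the best-validation
#' parameters (early stopping on patience).
#'
#' @param md a `model_data` from [prepare_model_data()].
#' @param train_idx,val_idx record index sets; when `val_idx` is NULL the
#'   final-epoch parameters are returned.
#' @param train_cfg a [train_config()].
#' @param params optional warm-start generator parameters.
#' @return list with `params` (best), `history` (per-epoch data frame),
#'   `best_val_mse`, `best_epoch`.
#' @export
pretrain <- function(md, train_idx, val_idx = NULL, train_cfg = train_config(),
                     params = NULL) {
  stopifnot(inherits(md, "model_data"), length(train_idx) > 0)
  cfg <- md$cfg
  params <- params %||%
    init_generator_params(md$vocab_d, md$vocab_p, cfg, seed = train_cfg$seed)
  opt <- adam_init(params)
  best <- list(val = Inf, params = params, epoch = 0L)
  hist <- data.frame()
  wait <- 0L
  for (epoch in seq_len(train_cfg$pretrain_epochs)) {
    set.seed(derive_seed(train_cfg$seed, 1000L, epoch))
    ord <- sample(train_idx)
    tr_loss <- 0; n_seen <- 0L
    for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
      sub <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
      batch <- make_seq_batch(md, sub)
      mask <- NULL
      if (cfg$dropout > 0) {
        mask <- matrix(stats::rbinom(length(sub) * 3L * cfg$width, 1L,
                                     1 - cfg$dropout) / (1 - cfg$dropout),
                       length(sub), 3L * cfg$width)
      }
      fw <- gen_forward(batch, params, cfg, dropout_mask = mask)
      resid <- fw$pred - batch$y
      if (!all(is.finite(resid))) stop("divergence: non-finite loss")
      tr_loss <- tr_loss + sum(resid^2); n_seen <- n_seen + length(sub)
      grads <- gen_backward(2 * resid / length(sub), fw, params, cfg)
      st <- adam_step(params, grads, opt, lr = train_cfg$lr,
                      weight_decay = train_cfg$weight_decay)
      params <- st$params; opt <- st$state
    }
    val_mse <- NA_real_
    if (!is.null(val_idx) && length(val_idx) > 0) {
      vp <- seq_predict_all(params, md, val_idx)
      val_mse <- mean((vp - md$records$affinity[val_idx])^2)
      if (val_mse < best$val) {
        best <- list(val = val_mse, params = params, epoch = epoch)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_mse = tr_loss / n_seen,
                                   val_mse = val_mse))
    if (!is.null(val_idx) && wait >= train_cfg$patience) break
  }
  if (is.null(val_idx)) best <- list(val = NA_real_, params = params,
                                     epoch = nrow(hist))
  list(params = best$params, history = hist, best_val_mse = best$val,
       best_epoch = best$epoch)
}

#' Jointly train the feature generator and the hybrid GNN
#'
#' Every `update_interval` epochs the layer-normalized node features are
#' recomputed from the current generator and cached; between refreshes the
#' GNN trains on the cached features while the generator receives gradient
#' through the sequence branch of the ensembled prediction. Returns the
#' best-validation model.
#'
#' @param md a `model_data`.
#' @param train_idx,val_idx record index sets.
#' @param gin_cfg a [gin_config()].
#' @param train_cfg a [train_config()].
#' @param gen_params pretrained generator parameters; when NULL the
#'   generator is pre-trained first with the same configuration.
#' @return a `dta_model`: list with configs, vocabularies, trained
#'   parameters, the ensemble gate, and the training history.
#' @export
joint_train <- function(md, train_idx, val_idx = NULL,
                        gin_cfg = gin_config(), train_cfg = train_config(),
                        gen_params = NULL) {
  cfg <- md$cfg
  pre_hist <- NULL; pre_best <- NA_real_
  if (is.null(gen_params)) {
    pt <- pretrain(md, train_idx, val_idx, train_cfg)
    gen_params <- pt$params
    pre_hist <- pt$history
    pre_best <- pt$best_val_mse
  }
  gnn_params <- init_gnn_params(gin_cfg, cfg$width, seed = train_cfg$seed)
  gnn_params$ens_alpha <- matrix(0, 1L, 1L)
  opt_g <- adam_init(gen_params)
  opt_n <- adam_init(gnn_params)
  mode <- train_cfg$ensemble_mode
  all_idx <- sort(unique(c(train_idx, val_idx)))
  feat_cache <- NULL
  best <- list(val = Inf, gen = gen_params, gnn = gnn_params, epoch = 0L)
  hist <- data.frame()
  wait <- 0L
  n_refreshes <- 0L
  for (epoch in seq_len(train_cfg$joint_epochs)) {
    if (epoch == 1L || (epoch - 1L) %% train_cfg$update_interval == 0L) {
      feat_cache <- refresh_node_features(gen_params, md, all_idx)
      n_refreshes <- n_refreshes + 1L
    }
    set.seed(derive_seed(train_cfg$seed, 2000L, epoch))
    ord <- sample(train_idx)
    tr_loss <- 0; n_seen <- 0L
    for (start in seq(1L, length(ord), by = train_cfg$batch_size)) {
      sub <- ord[start:min(start + train_cfg$batch_size - 1L, length(ord))]
      B <- length(sub)
      sb <- make_seq_batch(md, sub)
      fw_s <- gen_forward(sb, gen_params, cfg)
      gb <- make_graph_batch(md, sub, feat_cache)
      fw_g <- gnn_forward_batch(gb$A, gb$X, gb$graph_id, gb$central_rows,
                                gin_cfg, gnn_params)
      alpha <- gnn_params$ens_alpha[1, 1]
      w <- switch(mode, mean = 0.5, learned_weight = 1 / (1 + exp(-alpha)),
                  seq_only = 1, graph_only = 0)
      final <- w * fw_s$pred + (1 - w) * fw_g$pred
      resid <- final - sb$y
      if (!all(is.finite(resid))) stop("divergence: non-finite loss")
      tr_loss <- tr_loss + sum(resid^2); n_seen <- n_seen + B
      dfinal <- 2 * resid / B
      aux <- train_cfg$aux_branch_weight
      dseq <- dfinal * w + aux * 2 * (fw_s$pred - sb$y) / B
      dgra <- dfinal * (1 - w) + aux * 2 * (fw_g$pred - sb$y) / B
      if (!train_cfg$freeze_generator && any(dseq != 0)) {
        g_gen <- gen_backward(dseq, fw_s, gen_params, cfg)
        st <- adam_step(gen_params, g_gen, opt_g, lr = train_cfg$lr,
                        weight_decay = train_cfg$weight_decay)
        gen_params <- st$params; opt_g <- st$state
      }
      g_gnn <- if (any(dgra != 0)) {
        gnn_backward_batch(dgra, fw_g, gin_cfg, gnn_params)$grads
      } else list()
      if (mode == "learned_weight") {
        g_gnn$ens_alpha <- matrix(sum(dfinal * (fw_s$pred - fw_g$pred)) *
                                    w * (1 - w), 1L, 1L)
      }
      if (length(g_gnn) > 0) {
        st <- adam_step(gnn_params, g_gnn, opt_n, lr = train_cfg$lr,
                        weight_decay = train_cfg$weight_decay)
        gnn_params <- st$params; opt_n <- st$state
      }
    }
    val_mse <- NA_real_
    if (!is.null(val_idx) && length(val_idx) > 0) {
      sp <- seq_predict_all(gen_params, md, val_idx)
      gp <- graph_predict_all(gnn_params, gin_cfg, md, val_idx, feat_cache)
      alpha <- gnn_params$ens_alpha[1, 1]
      fp <- combine_predictions(sp, gp, mode, alpha)
      val_mse <- mean((fp - md$records$affinity[val_idx])^2)
      if (val_mse < best$val) {
        best <- list(val = val_mse, gen = gen_params, gnn = gnn_params,
                     epoch = epoch)
        wait <- 0L
      } else wait <- wait + 1L
    }
    hist <- rbind(hist, data.frame(epoch = epoch,
                                   train_mse = tr_loss / n_seen,
                                   val_mse = val_mse))
    if (!is.null(val_idx) && wait >= train_cfg$patience) break
  }
  if (is.null(val_idx)) best <- list(val = NA_real_, gen = gen_params,
                                     gnn = gnn_params, epoch = nrow(hist))
  structure(list(encoder_cfg = cfg, gin_cfg = gin_cfg, train_cfg = train_cfg,
                 vocab_d = md$vocab_d, vocab_p = md$vocab_p,
                 gen_params = best$gen, gnn_params = best$gnn,
                 contact_threshold = md$contact_threshold,
                 history = list(pretrain = pre_hist, joint = hist,
                                n_refreshes = n_refreshes),
                 pretrain_val_mse = pre_best, best_val_mse = best$val),
            class = "dta_model")
}

#' @export
print.dta_model <- function(x, ...) {
  cat("<dta_model> width", x$encoder_cfg$width, "|", x$gin_cfg$n_layers,
      "GIN layers | ensemble:", x$train_cfg$ensemble_mode, "\n")
  if (is.finite(x$best_val_mse))
    cat("  best validation MSE:", format(x$best_val_mse, digits = 4), "\n")
  invisible(x)
}

#' Predict affinities with a trained model
#'
#' Node features for the graph branch are computed fresh from the current
#' generator (evaluation mode); predictions are deterministic.
#'
#' @param model a `dta_model`.
#' @param data a `dta_dataset` (or `model_data` prepared with the model's
#'   vocabularies).
#' @param idx record indices (default: all).
#' @return data frame with `seq_pred`, `graph_pred`, `final_pred`.
#' @export
predict_affinity <- function(model, data, idx = NULL) {
  md <- if (inherits(data, "model_data")) data else
    prepare_model_data(data, model$encoder_cfg, model$vocab_d,
                       model$vocab_p, model$contact_threshold)
  idx <- idx %||% seq_len(nrow(md$records))
  sp <- seq_predict_all(model$gen_params, md, idx)
  feats <- refresh_node_features(model$gen_params, md, idx)
  gp <- graph_predict_all(model$gnn_params, model$gin_cfg, md, idx, feats)
  fp <- combine_predictions(sp, gp, model$train_cfg$ensemble_mode,
                            model$gnn_params$ens_alpha[1, 1])
  data.frame(seq_pred = sp, graph_pred = gp, final_pred = fp)
}

#' Save / load a model checkpoint
#'
#' A single file containing configs, weights and vocabularies,
#' version-stamped; a round trip reproduces predictions exactly.
#'
#' @param model a `dta_model`.
#' @param path checkpoint path.
#' @rdname checkpoint
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dta_model"))
  obj <- unclass(model)
  obj$.format_version <- 1L
  obj$.package_version <- as.character(utils::packageVersion("hybridDTA"))
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$.format_version))
    stop("not a model checkpoint: ", path)
  obj$.format_version <- NULL
  obj$.package_version <- NULL
  structure(obj, class = "dta_model")
}
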