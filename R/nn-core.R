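# Low-level numerical kernels shared by the sequence encoder and the GNN.
# All parameters live in flat named lists of base matrices so that the Adam
# optimiser and the finite-difference gradient checker can walk them
# generically.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
nn_relu <- function(x) {
  x[x < 0] <- 0
  x
}

# column-wise softmax of a score matrix (positions x heads)
#' @noRd
nn_softmax_cols <- function(s) {
  s <- sweep(s, 2L, apply(s, 2L, max), "-")
  e <- exp(s)
  sweep(e, 2L, colSums(e), "/")
}

# add a 1 x k bias row to every row of X
#' @noRd
nn_addb <- function(x, b) {
  x + rep(b, each = nrow(x))
}

# row-wise layer normalization (population variance, no learned affine)
#' @noRd
nn_layernorm_rows <- function(x, eps = 1e-8) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  list(y = xc / sd, sd = sd)
}

# backward of nn_layernorm_rows: dy -> dx given y and sd from the forward
#' @noRd
nn_layernorm_rows_bwd <- function(dy, y, sd) {
  m1 <- rowMeans(dy)
  m2 <- rowMeans(dy * y)
  (dy - m1 - y * m2) / sd
}

# normalize a single vector the same way (used for node features)
#' @noRd
nn_layernorm_vec <- function(x, eps = 1e-8) {
  xc <- x - mean(x)
  xc / sqrt(mean(xc^2) + eps)
}

#' @noRd
nn_init_mat <- function(nr, nc, scale = NULL) {
  scale <- scale %||% sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -scale, scale), nr, nc)
}

#' @noRd
nn_zeros <- function(nr, nc) matrix(0, nr, nc)

# dense layer stack: dims = c(d_in, hidden..., 1); returns named params
#' @noRd
nn_init_mlp <- function(prefix, dims) {
  p <- list()
  for (i in seq_len(length(dims) - 1L)) {
    p[[paste0(prefix, i, "_W")]] <- nn_init_mat(dims[i], dims[i + 1L])
    p[[paste0(prefix, i, "_b")]] <- nn_zeros(1L, dims[i + 1L])
  }
  p
}

# forward through a ReLU MLP; last layer linear. Returns output + caches.
#' @noRd
nn_mlp_forward <- function(x, params, prefix, n_layers) {
  acts <- vector("list", n_layers)
  h <- x
  for (i in seq_len(n_layers)) {
    z <- nn_addb(h %*% params[[paste0(prefix, i, "_W")]],
                 params[[paste0(prefix, i, "_b")]])
    if (i < n_layers) {
      acts[[i]] <- list(input = h, z = z)
      h <- nn_relu(z)
    } else {
      acts[[i]] <- list(input = h, z = z)
      h <- z
    }
  }
  list(out = h, acts = acts)
}

#' @noRd
nn_mlp_backward <- function(dout, cache, params, prefix, n_layers, grads) {
  g <- dout
  for (i in rev(seq_len(n_layers))) {
    a <- cache$acts[[i]]
    if (i < n_layers) g <- g * (a$z > 0)
    wname <- paste0(prefix, i, "_W")
    bname <- paste0(prefix, i, "_b")
    grads[[wname]] <- (grads[[wname]] %||% 0) + crossprod(a$input, g)
    grads[[bname]] <- (grads[[bname]] %||% 0) + matrix(colSums(g), 1L)
    g <- g %*% t(params[[wname]])
  }
  list(dx = g, grads = grads)
}

# --- Adam ------------------------------------------------------------------

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

# returns list(params, state); grads may omit parameters (treated as zero)
#' @noRd
adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (weight_decay > 0) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# deterministic child seed derivation, kept within 32-bit integer range
#' @noRd
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) s <- (s * 7919 + as.numeric(k) + 1) %% 2147483629
  as.integer(s)
}
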