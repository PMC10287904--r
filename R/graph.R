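# Construction of the drug bond graph, the protein contact-map graph, and
# the hybrid graph that fuses them through a single central node.
#
# Node ordering convention throughout: protein residues first (0-based),
# then drug atoms, then the central node last. No self-loops anywhere: the
# GIN update already carries the (1 + eps) h_v self term.

#' Drug bond graph from a SMILES string
#'
#' Nodes are heavy atoms in written (parser) order; one undirected edge per
#' covalent bond.
#'
#' @param smiles SMILES string.
#' @return a `drug_graph`: list with `n_atoms` and `edges` (two-column
#'   0-based index matrix with `i < j`, one row per undirected edge).
#' @export
drug_graph_from_smiles <- function(smiles) {
  p <- parse_smiles(smiles)
  e <- p$bonds - 1L
  if (nrow(e) > 0) {
    e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    e <- unique(e[e[, 1] != e[, 2], , drop = FALSE])
    e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  }
  structure(list(n_atoms = p$n_atoms, edges = e), class = "drug_graph")
}

#' Binarize a residue distance matrix into a contact map
#'
#' A residue pair (i, j), i < j, is a contact iff its distance is strictly
#' below `threshold` (pure thresholding; sequence-adjacent pairs get no
#' special treatment).
#'
#' @param dist square nonnegative distance matrix (Angstrom), symmetric with
#'   zero diagonal.
#' @param threshold contact threshold in Angstrom (default 8, the
#'   conventional C-beta cutoff).
#' @param tol symmetry tolerance.
#' @return a `contact_map`: list with `n_residues`, `contacts` (two-column
#'   0-based matrix, i < j) and `threshold`.
#' @export
contact_map_from_distances <- function(dist, threshold = 8, tol = 1e-6) {
  dist <- as.matrix(dist)
  if (nrow(dist) != ncol(dist)) stop("distance matrix is not square")
  if (max(abs(dist - t(dist))) > tol)
    stop("distance matrix is asymmetric beyond tolerance ", tol)
  n <- nrow(dist)
  idx <- which(upper.tri(dist) & dist < threshold, arr.ind = TRUE)
  contacts <- cbind(idx[, 1], idx[, 2]) - 1L
  contacts <- contacts[order(contacts[, 1], contacts[, 2]), , drop = FALSE]
  structure(list(n_residues = n, contacts = contacts, threshold = threshold),
            class = "contact_map")
}

#' Contact map from a precomputed binary matrix
#'
#' @param mat square 0/1 matrix.
#' @param threshold threshold recorded as provenance (not applied).
#' @return a `contact_map`.
#' @export
contact_map_from_binary <- function(mat, threshold = NA_real_) {
  mat <- as.matrix(mat)
  if (nrow(mat) != ncol(mat)) stop("contact matrix is not square")
  if (!all(mat %in% c(0, 1))) stop("binary contact matrix must be 0/1")
  if (any(mat != t(mat))) stop("contact matrix is asymmetric")
  idx <- which(upper.tri(mat) & mat == 1, arr.ind = TRUE)
  contacts <- cbind(idx[, 1], idx[, 2]) - 1L
  structure(list(n_residues = nrow(mat), contacts = contacts,
                 threshold = threshold),
            class = "contact_map")
}

#' Fuse protein and drug graphs through one central node
#'
#' The hybrid adjacency is block diagonal in the protein contact map and the
#' drug bond graph, with zero protein-drug cross blocks, plus one central
#' node (index `n_protein + n_drug`, 0-based last) adjacent to every other
#' node. The central node is the only path between the two molecules.
#'
#' @param Gp a `contact_map`.
#' @param Gd a `drug_graph`.
#' @return a `hybrid_graph`: list with `n_protein`, `n_drug`,
#'   `central_index` (0-based) and `edges` (two-column 0-based matrix).
#' @export
build_hybrid_graph <- function(Gp, Gd) {
  stopifnot(inherits(Gp, "contact_map"), inherits(Gd, "drug_graph"))
  np <- Gp$n_residues
  nd <- Gd$n_atoms
  if (np < 1L) stop("empty protein graph")
  if (nd < 1L) stop("empty drug graph")
  central <- np + nd
  e_p <- Gp$contacts
  e_d <- Gd$edges + np
  e_c <- cbind(0:(central - 1L), central)
  edges <- rbind(e_p, e_d, e_c)
  structure(list(n_protein = np, n_drug = nd, central_index = central,
                 edges = edges),
            class = "hybrid_graph")
}

#' Dense symmetric adjacency matrix of a hybrid graph
#'
#' @param hg a `hybrid_graph`.
#' @return binary matrix of size `n_protein + n_drug + 1`.
#' @export
hybrid_adjacency <- function(hg) {
  n <- hg$n_protein + hg$n_drug + 1L
  a <- matrix(0, n, n)
  e <- hg$edges + 1L
  a[e] <- 1
  a[e[, c(2, 1), drop = FALSE]] <- 1
  a
}

# sparse symmetric adjacency (Matrix) for batched GNN computation
#' @noRd
hybrid_adjacency_sparse <- function(edges, n) {
  if (nrow(edges) == 0)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  Matrix::sparseMatrix(i = c(edges[, 1], edges[, 2]) + 1L,
                       j = c(edges[, 2], edges[, 1]) + 1L,
                       x = 1, dims = c(n, n))
}

#' @export
print.hybrid_graph <- function(x, ...) {
  cat("<hybrid_graph>", x$n_protein, "residues +", x$n_drug,
      "atoms + 1 central |", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Serialize / restore a hybrid graph as an edge-list text file
#'
#' Format: a header line `n_protein n_drug`, then one `i j` pair (0-based)
#' per line.
#'
#' @param hg a `hybrid_graph`.
#' @param path file path.
#' @rdname hybrid_graph_io
#' @export
write_hybrid_graph <- function(hg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(hg$n_protein, hg$n_drug), con)
  if (nrow(hg$edges) > 0)
    writeLines(paste(hg$edges[, 1], hg$edges[, 2]), con)
  invisible(path)
}

#' @rdname hybrid_graph_io
#' @export
read_hybrid_graph <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(lines[1], "\\s+")[[1]])
  edges <- if (length(lines) > 1) {
    do.call(rbind, lapply(strsplit(lines[-1], "\\s+"), as.integer))
  } else matrix(integer(0), 0, 2)
  structure(list(n_protein = hdr[1], n_drug = hdr[2],
                 central_index = hdr[1] + hdr[2], edges = edges),
            class = "hybrid_graph")
}
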