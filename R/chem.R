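# Chemistry parsing via OpenBabel (ChemmineOB). OpenBabel enumerates heavy
# atoms in the order they are written in the input SMILES (no
# canonicalization) and leaves hydrogens implicit, which is exactly the
# shared ordering contract between the tokenizer and the graph builder.
# OpenBabel is lenient about malformed strings, so syntactic validation
# (balanced branches/brackets, paired ring closures, known characters) is
# done on our side before the structure is trusted.

.chem_cache <- new.env(parent = emptyenv())

# V2000 molblock -> atoms/bonds; the format is fixed-width
#' @noRd
parse_molblock <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) stop("empty molblock")
  counts <- lines[4]
  n_atoms <- as.integer(substr(counts, 1, 3))
  n_bonds <- as.integer(substr(counts, 4, 6))
  if (is.na(n_atoms) || n_atoms < 1L) stop("no atoms in molblock")
  atom_lines <- lines[4L + seq_len(n_atoms)]
  syms <- trimws(substr(atom_lines, 32, 34))
  bonds <- if (n_bonds > 0) {
    bl <- lines[4L + n_atoms + seq_len(n_bonds)]
    cbind(as.integer(substr(bl, 1, 3)), as.integer(substr(bl, 4, 6)))
  } else matrix(integer(0), 0, 2)
  list(symbols = syms, bonds = bonds)
}

# syntactic sanity that the lenient parser does not enforce
#' @noRd
smiles_syntax_ok <- function(smiles) {
  ok <- tryCatch({
    toks <- smiles_tokens(smiles)
    depth <- 0L
    rings <- character(0)
    for (tk in toks) {
      if (tk == "(") depth <- depth + 1L
      else if (tk == ")") {
        depth <- depth - 1L
        if (depth < 0L) stop("unbalanced branch")
      } else if (grepl("^[0-9]$", tk) || grepl("^%[0-9]{2}$", tk)) {
        if (tk %in% rings) rings <- setdiff(rings, tk)
        else rings <- c(rings, tk)
      }
    }
    depth == 0L && length(rings) == 0L && any(attr(toks, "is_atom"))
  }, error = function(e) FALSE)
  isTRUE(ok)
}

#' Parse a SMILES string into atoms and bonds
#'
#' @param smiles SMILES string.
#' @return list with `n_atoms` (heavy-atom count), `symbols` (element
#'   symbols in written order) and `bonds` (two-column 1-based index
#'   matrix, one row per covalent bond between heavy atoms).
#' @export
parse_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  hit <- .chem_cache[[smiles]]
  if (!is.null(hit)) return(hit)
  if (!smiles_syntax_ok(smiles))
    stop("SMILES failed to parse: ", smiles)
  mol <- tryCatch(
    parse_molblock(ChemmineOB::convertFormat("SMI", "SDF",
                                             paste0(smiles, "\n"))),
    error = function(e) NULL)
  if (is.null(mol)) stop("SMILES failed to parse: ", smiles)
  syms <- mol$symbols
  bonds <- mol$bonds
  heavy <- syms != "H"
  if (!all(heavy)) {    # drop explicit hydrogens, reindex heavy atoms
    idx <- cumsum(heavy)
    keep <- heavy[bonds[, 1]] & heavy[bonds[, 2]]
    bonds <- cbind(idx[bonds[keep, 1]], idx[bonds[keep, 2]])
    syms <- syms[heavy]
  }
  # the written token stream and the parser must agree on the heavy atoms,
  # otherwise the token<->atom alignment contract would be silently broken
  n_tok <- sum(attr(smiles_tokens(smiles), "is_atom"))
  if (n_tok != length(syms))
    stop("SMILES failed to parse: ", smiles,
         " (tokenizer sees ", n_tok, " heavy atoms, parser ", length(syms), ")")
  out <- list(n_atoms = length(syms), symbols = syms, bonds = bonds)
  .chem_cache[[smiles]] <- out
  out
}

#' Is a string a parseable SMILES with at least one heavy atom?
#'
#' @param smiles SMILES string.
#' @return logical scalar.
#' @export
is_valid_smiles <- function(smiles) {
  ok <- tryCatch(parse_smiles(smiles)$n_atoms >= 1L,
                 error = function(e) FALSE)
  isTRUE(ok)
}

#' Heavy-atom count of a molecule
#'
#' @param smiles SMILES string.
#' @return integer.
#' @export
heavy_atom_count <- function(smiles) parse_smiles(smiles)$n_atoms
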