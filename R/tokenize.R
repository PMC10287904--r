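# Atomic-level tokenization of SMILES and per-residue tokenization of
# protein sequences. Every atom token position carries an explicit map back
# to the heavy-atom (or residue) index, so encoder outputs can later be
# gathered as graph-node features.

CLS_TOKEN <- "[CLS]"
PAD_TOKEN <- "[PAD]"
UNK_TOKEN <- "[UNK]"

# Two-character organic-subset element symbols that must never be split.
.SMILES_TWO_CHAR <- c("Cl", "Br", "Si", "Se", "As", "Te", "Li", "Na", "Mg",
                      "Al", "Ca", "Fe", "Zn", "Cu", "Mn", "Sn")

# single-character atoms, aromatic forms included
.SMILES_ONE_CHAR <- c("B", "C", "N", "O", "P", "S", "F", "I", "H",
                      "b", "c", "n", "o", "p", "s")

#' Split a SMILES string into atomic-level tokens
#'
#' Bracket atoms (`[nH]`, `[O-]`, ...) and two-character element symbols
#' (`Cl`, `Br`, ...) are kept as single tokens; bond, branch, ring-closure
#' and stereo symbols become tokens of their own. The attribute
#' `is_atom` flags tokens that correspond to a heavy atom.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens with logical attribute `is_atom`.
#' @export
smiles_tokens <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L, nzchar(smiles))
  chars <- strsplit(smiles, "", fixed = TRUE)[[1]]
  n <- length(chars)
  toks <- character(0)
  atom <- logical(0)
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unclosed bracket atom in SMILES: ", smiles)
      tok <- paste(chars[i:j], collapse = "")
      # bracket hydrogen [H]/[2H] counts as hydrogen, not a heavy atom
      inner <- sub("^\\[[0-9]*", "", sub("\\]$", "", tok))
      heavy <- !grepl("^H[0-9+-]*$", inner)
      toks <- c(toks, tok); atom <- c(atom, heavy)
      i <- j + 1L
    } else if (i < n && paste0(ch, chars[i + 1L]) %in% .SMILES_TWO_CHAR) {
      toks <- c(toks, paste0(ch, chars[i + 1L])); atom <- c(atom, TRUE)
      i <- i + 2L
    } else if (ch %in% .SMILES_ONE_CHAR) {
      toks <- c(toks, ch); atom <- c(atom, ch != "H")
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop("truncated ring-closure label in SMILES: ", smiles)
      toks <- c(toks, paste(chars[i:(i + 2L)], collapse = ""))
      atom <- c(atom, FALSE)
      i <- i + 3L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\", "~", ".", "(", ")",
                         "@", "+") || grepl("[0-9]", ch)) {
      toks <- c(toks, ch); atom <- c(atom, FALSE)
      i <- i + 1L
    } else {
      stop("unrecognized character '", ch, "' in SMILES: ", smiles)
    }
  }
  attr(toks, "is_atom") <- atom
  toks
}

#' Build a token vocabulary from a corpus
#'
#' Ids are contiguous from 0 in first-occurrence order after the three
#' reserved special tokens: classification (`[CLS]` = 0), padding
#' (`[PAD]` = 1) and unknown (`[UNK]` = 2). Deterministic given corpus
#' order.
#'
#' @param corpus character vector of raw SMILES (kind = "drug") or
#'   amino-acid sequences (kind = "protein").
#' @param kind `"drug"` or `"protein"`.
#' @return an object of class `dta_vocab`: list with `token_to_id`
#'   (named integer vector), `kind`, and the three special token names.
#' @export
build_vocab <- function(corpus, kind = c("drug", "protein")) {
  kind <- match.arg(kind)
  if (length(corpus) == 0L) stop("empty corpus")
  toks <- character(0)
  if (kind == "drug") {
    for (s in corpus) {
      if (!is_valid_smiles(s)) stop("unparseable SMILES in corpus: ", s)
      toks <- c(toks, smiles_tokens(s))
    }
  } else {
    toks <- unlist(strsplit(corpus, "", fixed = TRUE), use.names = FALSE)
  }
  uniq <- unique(toks)
  all_tokens <- c(CLS_TOKEN, PAD_TOKEN, UNK_TOKEN, uniq)
  ids <- stats::setNames(seq_along(all_tokens) - 1L, all_tokens)
  structure(list(token_to_id = ids, kind = kind,
                 cls = CLS_TOKEN, pad = PAD_TOKEN, unk = UNK_TOKEN),
            class = "dta_vocab")
}

#' @export
print.dta_vocab <- function(x, ...) {
  cat("<dta_vocab> kind:", x$kind, "| size:", length(x$token_to_id), "\n")
  invisible(x)
}

#' Write / read a vocabulary as two-column text
#'
#' @param vocab a `dta_vocab`.
#' @param path file path.
#' @rdname vocab_io
#' @export
write_vocab <- function(vocab, path) {
  df <- data.frame(token = names(vocab$token_to_id),
                   id = unname(vocab$token_to_id))
  df <- df[order(df$id), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param kind kind recorded in the restored vocabulary.
#' @rdname vocab_io
#' @export
read_vocab <- function(path, kind = c("drug", "protein")) {
  kind <- match.arg(kind)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"),
                          quote = "", comment.char = "")
  ids <- stats::setNames(df$id, df$token)
  structure(list(token_to_id = ids, kind = kind,
                 cls = CLS_TOKEN, pad = PAD_TOKEN, unk = UNK_TOKEN),
            class = "dta_vocab")
}

.lookup_ids <- function(tokens, vocab, warn_unknown = TRUE) {
  ids <- unname(vocab$token_to_id[tokens])
  miss <- is.na(ids)
  if (any(miss)) {
    if (warn_unknown)
      warning("tokens not in vocabulary mapped to ", UNK_TOKEN, ": ",
              paste(unique(tokens[miss]), collapse = " "))
    ids[miss] <- vocab$token_to_id[[UNK_TOKEN]]
  }
  as.integer(ids)
}

.new_tokseq <- function(tokens, ids, node_index_map, kind) {
  structure(list(tokens = tokens, ids = ids,
                 node_index_map = node_index_map, kind = kind),
            class = "dta_tokseq")
}

#' Tokenize a drug SMILES at the atomic level
#'
#' Position 1 is always the classification token. `node_index_map` is a
#' named integer vector mapping token positions (1-based) to 0-based heavy
#' atom indices in the order the chemistry parser enumerates them (the
#' written SMILES order); bond/branch/ring tokens are unmapped.
#'
#' @param smiles SMILES string.
#' @param vocab drug `dta_vocab`.
#' @param max_len maximum number of tokens after the classification token
#'   (tail truncation).
#' @param validate check the SMILES with the chemistry parser first.
#' @return a `dta_tokseq`.
#' @export
tokenize_drug <- function(smiles, vocab, max_len = 100L, validate = TRUE) {
  stopifnot(inherits(vocab, "dta_vocab"), vocab$kind == "drug")
  if (validate && !is_valid_smiles(smiles))
    stop("invalid SMILES: ", smiles)
  toks <- smiles_tokens(smiles)
  is_atom <- attr(toks, "is_atom")
  if (length(toks) > max_len) {
    toks <- toks[seq_len(max_len)]
    is_atom <- is_atom[seq_len(max_len)]
  }
  if (!any(is_atom)) stop("SMILES has no heavy atom: ", smiles)
  tokens <- c(CLS_TOKEN, as.character(toks))
  ids <- c(vocab$token_to_id[[CLS_TOKEN]], .lookup_ids(toks, vocab))
  pos <- which(is_atom) + 1L          # token positions of heavy atoms
  map <- stats::setNames(seq_along(pos) - 1L, pos)
  .new_tokseq(tokens, ids, map, "drug")
}

#' Tokenize a protein sequence per residue
#'
#' @param sequence uppercase one-letter amino-acid string.
#' @param vocab protein `dta_vocab`.
#' @param max_len maximum number of residue tokens (tail truncation).
#' @return a `dta_tokseq`; `node_index_map` maps token position i+1 to
#'   residue index i (0-based) for every residue.
#' @export
tokenize_protein <- function(sequence, vocab, max_len = 1000L) {
  stopifnot(inherits(vocab, "dta_vocab"), vocab$kind == "protein")
  if (!nzchar(sequence)) stop("empty protein sequence")
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (length(res) > max_len) res <- res[seq_len(max_len)]
  tokens <- c(CLS_TOKEN, res)
  ids <- c(vocab$token_to_id[[CLS_TOKEN]], .lookup_ids(res, vocab))
  map <- stats::setNames(seq_along(res) - 1L, seq_along(res) + 1L)
  .new_tokseq(tokens, ids, map, "protein")
}

#' @export
print.dta_tokseq <- function(x, ...) {
  cat("<dta_tokseq>", x$kind, "|", length(x$tokens), "tokens |",
      length(x$node_index_map), "mapped nodes\n")
  invisible(x)
}
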