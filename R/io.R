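# Readers and writers for the standard text formats: delimited affinity
# tables (CSV/TSV autodetected), FASTA protein sequences, whitespace
# square distance matrices, and prediction tables.

#' Read a delimited affinity table
#'
#' The table must name a SMILES, a protein-sequence and an affinity column
#' (names configurable). Rows failing validation (unparseable SMILES,
#' non-standard residues, non-finite affinity) are reported with their
#' line numbers and skipped, or abort when `strict = TRUE`.
#'
#' @param path CSV or TSV file (delimiter autodetected).
#' @param smiles_col,sequence_col,affinity_col column names.
#' @param drug_id_col,protein_id_col optional identifier columns; generated
#'   from the values when absent.
#' @param strict abort on the first invalid row instead of skipping.
#' @return data frame of validated records (class `affinity_table`).
#' @export
read_affinity_table <- function(path, smiles_col = "smiles",
                                sequence_col = "sequence",
                                affinity_col = "affinity",
                                drug_id_col = "drug_id",
                                protein_id_col = "protein_id",
                                strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (nrow(dt) == 0L) stop("empty affinity table: ", path)
  need <- c(smiles_col, sequence_col, affinity_col)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0)
    stop("missing required columns: ", paste(missing_cols, collapse = ", "))
  smiles <- as.character(dt[[smiles_col]])
  seqs <- toupper(as.character(dt[[sequence_col]]))
  aff <- suppressWarnings(as.numeric(dt[[affinity_col]]))
  bad <- character(0)
  ok <- rep(TRUE, nrow(dt))
  for (i in seq_len(nrow(dt))) {
    reason <- NULL
    if (!is.finite(aff[i])) reason <- "non-finite affinity"
    else if (!grepl("^[A-Z]+$", seqs[i])) reason <- "invalid residue characters"
    else if (!is_valid_smiles(smiles[i])) reason <- "unparseable SMILES"
    if (!is.null(reason)) {
      msg <- sprintf("line %d: %s (%s)", i + 1L, reason, smiles[i])
      if (strict) stop(msg)
      bad <- c(bad, msg)
      ok[i] <- FALSE
    }
  }
  if (length(bad) > 0)
    warning("skipped ", length(bad), " invalid rows:\n",
            paste(bad, collapse = "\n"))
  if (!any(ok)) stop("no valid rows in ", path)
  out <- data.frame(
    drug_id = if (drug_id_col %in% names(dt)) as.character(dt[[drug_id_col]][ok])
              else paste0("D", as.integer(factor(smiles[ok], levels = unique(smiles[ok])))),
    smiles = smiles[ok],
    protein_id = if (protein_id_col %in% names(dt))
                   as.character(dt[[protein_id_col]][ok])
                 else paste0("P", as.integer(factor(seqs[ok], levels = unique(seqs[ok])))),
    sequence = seqs[ok],
    affinity = aff[ok],
    stringsAsFactors = FALSE)
  class(out) <- c("affinity_table", "data.frame")
  out
}

#' Read a whitespace-delimited square distance (or binary contact) matrix
#'
#' @param path text file, one matrix row per line.
#' @return numeric matrix.
#' @export
read_distance_matrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  m
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readAAStringSet(path)
    out <- stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  id <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1),
                 collapse = "")
  stats::setNames(toupper(seqs), id)
}

#' Assemble a dataset from an affinity table and distance matrices
#'
#' @param records an `affinity_table` (or compatible data frame).
#' @param distmap_dir directory with one `<protein_id>.txt` square matrix
#'   per protein; `NULL` means contact maps must be supplied elsewhere.
#' @param fasta optional FASTA file; sequences are joined by `protein_id`
#'   and override (or supply) the table's sequence column.
#' @param contact_threshold threshold passed to
#'   [contact_map_from_distances()] downstream (recorded on the dataset).
#' @return a `dta_dataset`.
#' @export
dataset_from_table <- function(records, distmap_dir = NULL, fasta = NULL,
                               contact_threshold = 8) {
  if (!is.null(fasta)) {
    seqs <- read_fasta_sequences(fasta)
    miss <- setdiff(unique(records$protein_id), names(seqs))
    if (length(miss) > 0)
      stop("proteins missing from FASTA: ", paste(miss, collapse = ", "))
    records$sequence <- unname(seqs[records$protein_id])
  }
  drug_ids <- unique(records$drug_id)
  prot_ids <- unique(records$protein_id)
  drugs <- stats::setNames(lapply(drug_ids, function(d) {
    list(smiles = records$smiles[match(d, records$drug_id)])
  }), drug_ids)
  proteins <- stats::setNames(lapply(prot_ids, function(p) {
    seq <- records$sequence[match(p, records$protein_id)]
    dist <- NULL
    if (!is.null(distmap_dir)) {
      f <- file.path(distmap_dir, paste0(p, ".txt"))
      if (!file.exists(f)) stop("no distance matrix for protein ", p)
      dist <- read_distance_matrix(f)
    }
    list(sequence = seq, dist = dist)
  }), prot_ids)
  structure(list(records = as.data.frame(records), drugs = drugs,
                 proteins = proteins, truth = NULL,
                 contact_threshold = contact_threshold),
            class = "dta_dataset")
}

#' Write predictions next to their input records
#'
#' @param records input data frame.
#' @param preds data frame with `seq_pred`, `graph_pred`, `final_pred`.
#' @param path output TSV path.
#' @export
write_predictions <- function(records, preds, path) {
  out <- cbind(as.data.frame(records), preds)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
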