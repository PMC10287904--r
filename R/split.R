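# Dataset splitting: random pair splits and the three cold-start schemes
# (unseen drugs, unseen proteins, both). Fractional sizes are resolved by
# largest-remainder rounding with leftovers going to training.

#' Split specification
#'
#' @param scheme `"random"`, `"cold_drug"`, `"cold_target"` or
#'   `"all_cold"`.
#' @param fractions train/val/test fractions summing to 1.
#' @param seed RNG seed.
#' @return a `split_spec` list.
#' @export
split_spec <- function(scheme = c("random", "cold_drug", "cold_target",
                                  "all_cold"),
                       fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  scheme <- match.arg(scheme)
  stopifnot(length(fractions) == 3L, all(fractions > 0),
            abs(sum(fractions) - 1) < 1e-9)
  structure(list(scheme = scheme, fractions = fractions,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# largest-remainder apportionment of n items into three roles; leftover
# units go to the earliest role (training first)
#' @noRd
apportion <- function(n, fractions) {
  raw <- fractions * n
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    rem <- raw - base
    ord <- order(-rem, seq_along(rem))      # ties: training first
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# partition a vector of unique entities into three roles
#' @noRd
partition_entities <- function(entities, fractions) {
  n <- length(entities)
  sizes <- apportion(n, fractions)
  perm <- sample(entities)
  list(train = perm[seq_len(sizes[1])],
       val = perm[sizes[1] + seq_len(sizes[2])],
       test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
}

#' Split affinity records into train/validation/test index sets
#'
#' `random` partitions pairs; `cold_drug` partitions distinct drugs and
#' assigns pairs by drug; `cold_target` likewise by protein; `all_cold`
#' partitions drugs and proteins independently, keeps only pairs whose
#' drug and protein fall in the same role, and discards crossing pairs.
#'
#' @param records data frame with `drug_id` and `protein_id` columns (any
#'   identifier; SMILES and sequences work too).
#' @param spec a [split_spec()].
#' @return list of integer index vectors `train`, `val`, `test` (disjoint).
#' @export
make_split <- function(records, spec) {
  stopifnot(inherits(spec, "split_spec"), nrow(records) > 0)
  set.seed(derive_seed(spec$seed, 97L))
  n <- nrow(records)
  if (spec$scheme == "random") {
    sizes <- apportion(n, spec$fractions)
    perm <- sample.int(n)
    out <- list(train = perm[seq_len(sizes[1])],
                val = perm[sizes[1] + seq_len(sizes[2])],
                test = perm[sizes[1] + sizes[2] + seq_len(sizes[3])])
  } else if (spec$scheme %in% c("cold_drug", "cold_target")) {
    key <- if (spec$scheme == "cold_drug") records$drug_id else
      records$protein_id
    ents <- unique(key)
    if (length(ents) < 3L)
      stop("need at least 3 distinct entities for a cold split")
    part <- partition_entities(ents, spec$fractions)
    out <- lapply(part, function(e) which(key %in% e))
  } else {
    dents <- unique(records$drug_id)
    pents <- unique(records$protein_id)
    if (length(dents) < 3L || length(pents) < 3L)
      stop("need at least 3 distinct drugs and proteins for all_cold")
    dpart <- partition_entities(dents, spec$fractions)
    ppart <- partition_entities(pents, spec$fractions)
    role_of <- function(x, part) {
      r <- rep(NA_character_, length(x))
      for (nm in names(part)) r[x %in% part[[nm]]] <- nm
      r
    }
    dr <- role_of(records$drug_id, dpart)
    pr <- role_of(records$protein_id, ppart)
    out <- list(train = which(dr == "train" & pr == "train"),
                val = which(dr == "val" & pr == "val"),
                test = which(dr == "test" & pr == "test"))
  }
  lapply(out, function(i) sort(as.integer(i)))
}

#' Audit a split for entity leakage
#'
#' @param records the data frame used for [make_split()].
#' @param split the returned index sets.
#' @return list with the pairwise drug and protein overlaps between roles
#'   (all zero for the matching cold scheme) and a disjointness flag.
#' @export
audit_split <- function(records, split) {
  roles <- names(split)
  ov <- function(col) {
    sets <- lapply(split, function(i) unique(records[[col]][i]))
    out <- list()
    for (a in seq_along(roles)) for (b in seq_along(roles)) if (a < b) {
      out[[paste(roles[a], roles[b], sep = "-")]] <-
        length(intersect(sets[[a]], sets[[b]]))
    }
    out
  }
  idx <- unlist(split)
  list(drug_overlap = ov("drug_id"), protein_overlap = ov("protein_id"),
       disjoint = !anyDuplicated(idx))
}

#' Export / import split assignments as three-column text
#'
#' Columns: record index (1-based), role, and a header line recording the
#' seed and scheme, so external methods can be compared on identical
#' partitions.
#'
#' @param split index sets from [make_split()].
#' @param spec the [split_spec()] used.
#' @param path file path.
#' @rdname split_io
#' @export
write_split <- function(split, spec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# scheme=", spec$scheme, " seed=", spec$seed), con)
  for (role in names(split))
    writeLines(paste(split[[role]], role), con)
  invisible(path)
}

#' @rdname split_io
#' @export
read_split <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\\s+")
  idx <- vapply(parts, function(x) as.integer(x[1]), integer(1))
  role <- vapply(parts, `[`, character(1), 2)
  lapply(stats::setNames(nm = c("train", "val", "test")),
         function(r) sort(idx[role == r]))
}
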