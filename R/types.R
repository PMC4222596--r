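#' The 21-letter alphabet used throughout the package
#'
#' Twenty amino acids in alphabetical one-letter order followed by the gap
#' character. Profile columns, mutual-information joint distributions and
#' background frequencies all use this ordering.
#'
#' @export
aa_alphabet <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Construct a contact map
#'
#' A contact map records, for an L-residue chain, which unordered residue
#' pairs are in contact (Cbeta-Cbeta distance, Calpha for glycine, at most
#' the cutoff). Pairs for which either residue has no usable coordinates are
#' masked and are never counted as contact or non-contact by the evaluation
#' functions.
#'
#' @param map logical L x L matrix; `TRUE` marks a contact.
#' @param mask logical L x L matrix; `TRUE` marks pairs excluded from
#'   evaluation (unresolved residues). Defaults to no masking.
#' @return An object of class `contact_map` with elements `length`, `map`
#'   and `mask`. The matrix is symmetrised with an all-`FALSE` diagonal.
#' @export
contact_map <- function(map, mask = NULL) {
  map <- as.matrix(map)
  if (nrow(map) != ncol(map)) abort("contact map must be square")
  storage.mode(map) <- "logical"
  map[is.na(map)] <- FALSE
  map <- map | t(map)
  diag(map) <- FALSE
  L <- nrow(map)
  if (is.null(mask)) {
    mask <- matrix(FALSE, L, L)
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == L)) abort("mask must match map dimensions")
    storage.mode(mask) <- "logical"
    mask <- mask | t(mask)
  }
  diag(mask) <- TRUE
  structure(list(length = L, map = map, mask = mask), class = "contact_map")
}

#' Construct a prediction map
#'
#' A symmetric L x L matrix of real-valued contact scores or probabilities
#' produced by one base predictor or one stack layer. The diagonal is
#' ignored by all consumers and stored as zero.
#'
#' @param scores numeric L x L matrix (or upper triangle; it is mirrored).
#' @param method provenance label, e.g. `"MI"` or `"layer_3"`.
#' @return An object of class `prediction_map`.
#' @export
prediction_map <- function(scores, method = "unknown") {
  scores <- as.matrix(scores)
  if (nrow(scores) != ncol(scores)) abort("prediction map must be square")
  storage.mode(scores) <- "double"
  if (any(!is.finite(scores))) abort("prediction map scores must be finite")
  up <- upper.tri(scores)
  lo <- lower.tri(scores)
  if (all(scores[lo] == 0) && any(scores[up] != 0)) {
    scores[lo] <- t(scores)[lo]
  } else {
    scores <- (scores + t(scores)) / 2
  }
  diag(scores) <- 0
  structure(list(length = nrow(scores), scores = scores, method = method),
            class = "prediction_map")
}

#' Construct a multiple sequence alignment object
#'
#' @param rows character vector of aligned sequences (equal length, 20 amino
#'   acids plus `-`), or a character matrix of single residues.
#' @param ids sequence identifiers; defaults to `seq_1 ...`.
#' @return An object of class `msa` with elements `ids`, `seqs` (character
#'   matrix, one row per sequence) and `ncol`.
#' @export
msa <- function(rows, ids = NULL) {
  if (is.matrix(rows)) {
    seqs <- rows
  } else {
    if (length(unique(nchar(rows))) != 1L) {
      abort("alignment rows must all have the same length")
    }
    seqs <- do.call(rbind, strsplit(toupper(rows), ""))
  }
  seqs[seqs == "."] <- "-"
  if (is.null(ids)) ids <- paste0("seq_", seq_len(nrow(seqs)))
  if (length(ids) != nrow(seqs)) abort("one id per row required")
  structure(list(ids = as.character(ids), seqs = seqs, ncol = ncol(seqs)),
            class = "msa")
}

#' Number of rows of an alignment
#' @param x an [msa] object.
#' @return integer count of aligned sequences.
#' @export
n_sequences <- function(x) {
  stopifnot(inherits(x, "msa"))
  nrow(x$seqs)
}

#' Bundle one protein family for training or prediction
#'
#' Collects everything one chain contributes to the stack: the base
#' prediction maps, the per-residue feature tables, and (for training or
#' evaluation) the true contact map.
#'
#' @param base_maps list of [prediction_map] objects, all of the same length.
#' @param truth optional [contact_map] (required for training/evaluation).
#' @param pssm optional L x 21 profile matrix (see [compute_pssm]).
#' @param ss optional L x 3 matrix of secondary-structure class
#'   probabilities (helix, strand, coil).
#' @param rsa optional L x 5 matrix: relative surface accessibility, its
#'   reliability (z-score), and three secondary-structure probabilities.
#' @param ss_string optional per-residue class labels in `H`/`E`/`C`.
#' @param meff optional effective-sequence count of the family alignment.
#' @param id family identifier.
#' @return An object of class `contact_family`.
#' @export
contact_family <- function(base_maps, truth = NULL, pssm = NULL, ss = NULL,
                           rsa = NULL, ss_string = NULL, meff = NA_real_,
                           id = "family") {
  if (!is.list(base_maps) || length(base_maps) == 0) {
    abort("at least one base prediction map is required")
  }
  ok <- vapply(base_maps, inherits, logical(1), "prediction_map")
  if (!all(ok)) abort("base_maps must be prediction_map objects")
  L <- base_maps[[1]]$length
  if (!all(vapply(base_maps, function(m) m$length, integer(1)) == L)) {
    abort("all base maps must have the same length")
  }
  if (!is.null(truth)) {
    stopifnot(inherits(truth, "contact_map"))
    if (truth$length != L) abort("truth length disagrees with base maps")
  }
  chk <- function(m, k, what) {
    if (is.null(m)) return(NULL)
    m <- as.matrix(m)
    if (nrow(m) != L || ncol(m) != k) {
      abort(sprintf("%s table must be %d x %d", what, L, k))
    }
    storage.mode(m) <- "double"
    m
  }
  structure(list(
    id = id, length = L, base_maps = base_maps, truth = truth,
    pssm = chk(pssm, 21L, "pssm"), ss = chk(ss, 3L, "ss"),
    rsa = chk(rsa, 5L, "rsa"),
    ss_string = if (!is.null(ss_string)) as.character(ss_string) else NULL,
    meff = meff), class = "contact_family")
}

#' @export
print.contact_map <- function(x, ...) {
  n_up <- sum(x$map[upper.tri(x$map)])
  cat(sprintf("<contact_map> L = %d, %d contacts (%.1f%% of pairs), %d masked pairs\n",
              x$length, n_up, 100 * n_up / choose(x$length, 2),
              sum(x$mask[upper.tri(x$mask)])))
  invisible(x)
}

#' @export
print.prediction_map <- function(x, ...) {
  up <- x$scores[upper.tri(x$scores)]
  cat(sprintf("<prediction_map> L = %d, method = %s, score range [%.3g, %.3g]\n",
              x$length, x$method, min(up), max(up)))
  invisible(x)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences x %d columns (query: %s)\n",
              nrow(x$seqs), x$ncol, x$ids[1]))
  invisible(x)
}

#' @export
print.contact_family <- function(x, ...) {
  cat(sprintf("<contact_family> %s: L = %d, %d base maps%s%s\n",
              x$id, x$length, length(x$base_maps),
              if (!is.null(x$truth)) ", with truth" else "",
              if (!is.na(x$meff)) sprintf(", Meff = %.0f", x$meff) else ""))
  invisible(x)
}

# internal: upper-triangle index pairs (i < j) with separation >= min_sep
eligible_pairs <- function(L, min_sep = 5L, mask = NULL) {
  idx <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  keep <- (idx[, 2] - idx[, 1]) >= min_sep
  if (!is.null(mask)) keep <- keep & !mask[idx]
  idx <- idx[keep, , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}
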