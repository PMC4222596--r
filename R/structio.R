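#' Read residue coordinates for one chain of a PDB file
#'
#' Extracts, for every residue of the requested chain, the coordinate used
#' by the CASP contact definition: the Cbeta atom, or Calpha for glycine.
#' Non-glycine residues whose Cbeta is missing fall back to Calpha; residues
#' with neither atom are kept in sequence but flagged absent so that the
#' pairs they participate in can be masked rather than imputed. When a
#' residue has alternate conformers the highest-occupancy one wins (first
#' encountered on ties). Insertion-coded residues sort after their base
#' residue number.
#'
#' @param path PDB file.
#' @param chain chain identifier (single character).
#' @return A tibble with one row per residue: `residue_index` (1-based
#'   position along the chain), `resno`, `insert`, `amino_acid` (one-letter
#'   code), `x`, `y`, `z`, `source` (`"CA"` or `"CB"`) and `present`.
#' @seealso [contact_map_from_coords()]
#' @export
read_structure <- function(path, chain) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  chains <- unique(at$chain)
  if (!chain %in% chains) {
    abort(sprintf("chain '%s' not found (available: %s)", chain,
                  paste(chains, collapse = ", ")))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  ins <- at$insert
  ins[is.na(ins)] <- ""
  at$insert <- ins
  key <- paste(at$resno, at$insert, sep = "|")
  # residue order: residue number, then insertion code after the base
  first_seen <- match(unique(key), key)
  ord_keys <- unique(key)[order(at$resno[first_seen], at$insert[first_seen])]

  pick_atom <- function(rows, name) {
    cand <- rows[rows$elety == name, , drop = FALSE]
    if (nrow(cand) == 0) return(NULL)
    occ <- cand$o
    occ[is.na(occ)] <- 1
    cand[which.max(occ), , drop = FALSE]  # ties: first encountered
  }

  res <- purrr::map(ord_keys, function(k) {
    rows <- at[key == k, , drop = FALSE]
    aa <- bio3d::aa321(rows$resid[1])
    if (is.na(aa)) aa <- "X"
    ca <- pick_atom(rows, "CA")
    cb <- pick_atom(rows, "CB")
    use <- if (identical(aa, "G")) ca else (cb %||% ca)
    tibble::tibble(
      resno = rows$resno[1], insert = rows$insert[1], amino_acid = aa,
      x = if (is.null(use)) NA_real_ else use$x,
      y = if (is.null(use)) NA_real_ else use$y,
      z = if (is.null(use)) NA_real_ else use$z,
      source = if (is.null(use)) NA_character_ else use$elety,
      present = !is.null(use))
  })
  out <- dplyr::bind_rows(res)
  if (!any(out$present)) abort(sprintf("chain '%s' has no usable residues", chain))
  dplyr::mutate(out, residue_index = dplyr::row_number(), .before = 1)
}

#' Derive a contact map from residue coordinates
#'
#' Two residues are in contact when the Euclidean distance between their
#' representative atoms (Cbeta, Calpha for glycine) is at most `cutoff`
#' Angstrom; the boundary value itself counts as a contact. Pairs involving
#' a residue without usable coordinates are masked.
#'
#' @param coords tibble from [read_structure()] (columns `x`, `y`, `z`,
#'   `present`), or any data frame with those columns.
#' @param cutoff contact distance threshold in Angstrom; default 8.
#' @return A [contact_map].
#' @export
contact_map_from_coords <- function(coords, cutoff = 8.0) {
  if (cutoff <= 0) abort("cutoff must be positive")
  if (sum(coords$present) < 2) abort("need at least two residues with coordinates")
  L <- nrow(coords)
  d <- as.matrix(dist(cbind(coords$x, coords$y, coords$z)))
  map <- !is.na(d) & d <= cutoff
  absent <- !coords$present
  mask <- outer(absent, absent, "|")
  map[mask] <- FALSE  # masked pairs carry no contact call at all
  contact_map(map, mask)
}

#' Write and read contact predictions in CASP RR format
#'
#' `write_rr()` serialises the strictly positive scores of a prediction map
#' as `i j d1 d2 score` records (1-based, `i < j`, distance bounds fixed at
#' 0 and 8), sorted by descending score, after a `PFRMAT RR` header and an
#' optional sequence block. `read_rr()` parses the same format, accepts
#' records with `j < i` (normalised on read), and reports malformed lines
#' with their line number. Scores are written with six decimals; a
#' write/read round trip is exact at that precision.
#'
#' @param map a [prediction_map].
#' @param seq optional amino-acid sequence written into the header block.
#' @param path output (input) file.
#' @param length chain length for `read_rr()`; inferred from the sequence
#'   block or the largest residue index when omitted.
#' @return `write_rr()` returns `path` invisibly; `read_rr()` a
#'   [prediction_map].
#' @export
write_rr <- function(map, seq = NULL, path) {
  stopifnot(inherits(map, "prediction_map"))
  lines <- c("PFRMAT RR")
  if (!is.null(seq)) {
    s <- paste(seq, collapse = "")
    lines <- c(lines, substring(s, seq(1, nchar(s), 50),
                                pmin(seq(1, nchar(s), 50) + 49, nchar(s))))
  }
  idx <- which(upper.tri(map$scores) & map$scores > 0, arr.ind = TRUE)
  if (nrow(idx) > 0) {
    sc <- map$scores[idx]
    ord <- order(-sc, idx[, 1], idx[, 2])
    lines <- c(lines, sprintf("%d %d 0 8 %.6f",
                              idx[ord, 1], idx[ord, 2], sc[ord]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_rr
#' @export
read_rr <- function(path, length = NULL) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path)
  seq_chars <- character(0)
  records <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || line == "END") next
    if (grepl("^(PFRMAT|TARGET|AUTHOR|METHOD|MODEL|REMARK)", line)) next
    if (grepl("^[A-Za-z-]+$", line)) {
      seq_chars <- c(seq_chars, line)
      next
    }
    f <- strsplit(line, "\\s+")[[1]]
    v <- suppressWarnings(as.numeric(f))
    if (!(length(f) %in% c(3L, 5L)) || any(is.na(v))) {
      abort(sprintf("malformed RR record at line %d: '%s'", ln, lines[ln]))
    }
    records[[length(records) + 1L]] <- c(v[1], v[2], v[length(v)])
  }
  rec <- if (length(records)) do.call(rbind, records) else matrix(0, 0, 3)
  L <- length %||%
    (if (nchar(paste(seq_chars, collapse = "")) > 0) {
       nchar(paste(seq_chars, collapse = ""))
     } else if (nrow(rec) > 0) max(rec[, 1:2]) else 0L)
  if (L < 1) abort("cannot infer chain length from an empty RR file; pass `length`")
  if (nrow(rec) > 0 && (any(rec[, 1:2] < 1) || any(rec[, 1:2] > L))) {
    abort("RR record index outside 1..length")
  }
  scores <- matrix(0, L, L)
  if (nrow(rec) > 0) {
    ii <- pmin(rec[, 1], rec[, 2])
    jj <- pmax(rec[, 1], rec[, 2])
    scores[cbind(ii, jj)] <- rec[, 3]
    scores[cbind(jj, ii)] <- rec[, 3]
  }
  prediction_map(scores, method = "rr")
}
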