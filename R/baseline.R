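#' Mutual information between alignment columns
#'
#' For every column pair (i, j) the mutual information over the 21-state
#' alphabet is `sum_ab p(a,b) log(p(a,b) / (p(a) p(b)))` in nats, with joint
#' frequencies estimated from (optionally weighted) counts plus an additive
#' pseudocount per cell. Marginals are derived from the smoothed joint, so
#' MI is always non-negative. Intended to be run after [filter_gappy_rows()].
#'
#' @param x an [msa].
#' @param pseudocount additive count per joint cell; default `1/441`
#'   (one total pseudo-observation spread over the 21 x 21 table). At 0 the
#'   raw plug-in estimator is used with `0 log 0 = 0`.
#' @param weights optional per-row weights (e.g. from
#'   [effective_sequences()]); default unweighted.
#' @return A [prediction_map] (`method = "MI"`); diagonal zero.
#' @export
mutual_information <- function(x, pseudocount = 1 / 441, weights = NULL) {
  stopifnot(inherits(x, "msa"))
  n <- nrow(x$seqs)
  L <- x$ncol
  mi <- matrix(0, L, L)
  if (n < 2) {
    warn("single-row alignment: mutual information is identically zero")
    return(prediction_map(mi, method = "MI"))
  }
  w <- weights %||% rep(1, n)
  st <- matrix(match(x$seqs, aa_alphabet), n, L)
  if (any(is.na(st))) {
    # unknown characters carry no state information; treat as gap
    st[is.na(st)] <- 21L
  }
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      cell <- st[, i] + 21L * (st[, j] - 1L)
      agg <- rowsum(w, cell)
      joint <- matrix(pseudocount, 21L, 21L)
      joint[as.integer(rownames(agg))] <- joint[as.integer(rownames(agg))] + agg[, 1]
      p <- joint / sum(joint)
      pi_ <- rowSums(p)
      pj_ <- colSums(p)
      ratio <- p / outer(pi_, pj_)
      term <- p * log(ratio)
      mi[i, j] <- mi[j, i] <- sum(term[p > 0])
    }
  }
  prediction_map(pmax(mi, 0), method = "MI")
}

#' Average product correction of a coupling or MI map
#'
#' Subtracts the product of the row means divided by the grand mean from
#' every entry: `corrected(i,j) = raw(i,j) - rowmean(i) rowmean(j) / mean`,
#' with the diagonal excluded from all means. The correction removes
#' background signal that factorises over positions (e.g. per-column
#' entropy or phylogenetic weight); a map of exact product form
#' `u(i) u(j)` is corrected to zero off the diagonal.
#'
#' @param map a symmetric [prediction_map].
#' @return A [prediction_map] with `method` suffixed `"+APC"`. When the
#'   grand mean is zero the input is returned unchanged with a warning.
#' @export
apc_correct <- function(map) {
  stopifnot(inherits(map, "prediction_map"))
  L <- map$length
  s <- map$scores
  if (L < 2) return(map)
  off <- !diag(TRUE, L)
  rowmean <- rowSums(s * off) / (L - 1)
  grand <- mean(s[off])
  if (grand == 0) {
    warn("grand mean is zero; returning map unchanged")
    return(map)
  }
  corrected <- s - outer(rowmean, rowmean) / grand
  diag(corrected) <- 0
  prediction_map(corrected, method = paste0(map$method, "+APC"))
}

#' Load an externally produced contact score map
#'
#' Reads the two dialects that direct-coupling and sparse-inverse-covariance
#' programs commonly emit: a triplet list (`i j score`, 1-based, one pair
#' per line, unlisted pairs scored 0) or a whitespace-delimited dense L x L
#' matrix. Triplets are mirrored onto a symmetric matrix; a dense matrix
#' that is asymmetric beyond tolerance is rejected, small asymmetries are
#' averaged out.
#'
#' @param path input file.
#' @param dialect `"triplet"` or `"matrix"`.
#' @param length chain length L (required for triplets; checked for dense).
#' @param method_tag provenance label for the resulting map.
#' @param tol largest tolerated relative asymmetry of a dense matrix.
#' @return A [prediction_map].
#' @export
load_external_map <- function(path, dialect = c("triplet", "matrix"),
                              length = NULL, method_tag = "external",
                              tol = 1e-6) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (dialect == "triplet") {
    if (is.null(length)) abort("`length` is required for the triplet dialect")
    L <- as.integer(length)
    scores <- matrix(0, L, L)
    lines <- readLines(path)
    for (ln in seq_along(lines)) {
      line <- trimws(lines[ln])
      if (line == "" || grepl("^#", line)) next
      v <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1]]))
      if (length(v) < 3 || any(is.na(v[1:3]))) {
        abort(sprintf("malformed triplet at line %d: '%s'", ln, lines[ln]))
      }
      i <- v[1]; j <- v[2]
      if (i < 1 || j < 1 || i > L || j > L) {
        abort(sprintf("index outside 1..%d at line %d", L, ln))
      }
      scores[i, j] <- scores[j, i] <- v[3]
    }
    return(prediction_map(scores, method = method_tag))
  }
  m <- as.matrix(read.table(path))
  dimnames(m) <- NULL
  if (nrow(m) != ncol(m)) abort("dense map is not square")
  if (!is.null(length) && nrow(m) != length) {
    abort(sprintf("dense map is %d x %d but length = %d given",
                  nrow(m), ncol(m), length))
  }
  asym <- max(abs(m - t(m)))
  scale <- max(abs(m), 1)
  if (asym > tol * scale) {
    abort(sprintf("dense map asymmetric beyond tolerance (max |a - t(a)| = %g)", asym))
  }
  prediction_map((m + t(m)) / 2, method = method_tag)
}
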