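#' Background amino-acid frequencies
#'
#' Reference frequencies over the 21-state alphabet ([aa_alphabet]): the 20
#' amino acids at UniProt/Swiss-Prot-like composition plus a small constant
#' gap frequency, renormalised to sum to one. Used as the default profile
#' background.
#'
#' @return named numeric vector of length 21 summing to 1.
#' @export
default_background <- function() {
  f <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
         G = 0.0707, H = 0.0227, I = 0.0596, K = 0.0584, L = 0.0966,
         M = 0.0242, N = 0.0406, P = 0.0470, Q = 0.0393, R = 0.0553,
         S = 0.0657, T = 0.0534, V = 0.0687, W = 0.0108, Y = 0.0292)
  f <- c(f[aa_alphabet[1:20]], "-" = 0.01)
  f / sum(f)
}

#' Read an alignment from aligned FASTA or a3m
#'
#' Aligned FASTA files must have rows of equal length. In a3m, lowercase
#' letters mark insertions relative to the query; they are removed so that
#' every row aligns to the query coordinate system (`.` gap characters are
#' likewise dropped from a3m rows). The first row is taken as the query.
#'
#' @param path alignment file.
#' @param format `"fasta"`, `"a3m"`, or `"auto"` (by file extension;
#'   anything not ending in `.a3m` is treated as FASTA).
#' @return An [msa] object.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "a3m")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.a3m$", path, ignore.case = TRUE)) "a3m" else "fasta"
  }
  if (format == "fasta") {
    # bio3d pads ragged rows silently; verify record lengths up front
    raw <- readLines(path)
    hdr <- grepl("^>", raw)
    lens <- tapply(nchar(trimws(raw[!hdr])), cumsum(hdr)[!hdr], sum)
    if (length(unique(lens)) > 1L) {
      abort("ragged FASTA alignment: rows differ in length")
    }
    ali <- bio3d::read.fasta(path)
    m <- toupper(ali$ali)
    m[m == "."] <- "-"
    return(msa(m, ids = ali$id))
  }
  # a3m: rows are ragged until lowercase insertion states are removed
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) abort("not a FASTA/a3m file (no '>' header)")
  grp <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  rows <- vapply(split(lines[!hdr], grp[!hdr]), paste, character(1), collapse = "")
  rows <- gsub("[a-z.]", "", rows)
  if (length(unique(nchar(rows))) != 1L) {
    abort("a3m rows do not align to the query after insertion removal")
  }
  msa(unname(rows), ids = ids)
}

#' Pairwise sequence identity between two aligned rows
#'
#' Identity is the number of matching residues divided by the number of
#' compared columns. Columns gapped in both rows are skipped; a column
#' gapped in exactly one row is compared and counts as a mismatch.
#'
#' @param a,b aligned rows: equal-length strings or character vectors.
#' @return fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (length(a) == 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) abort("rows must have equal aligned length")
  both_gap <- a == "-" & b == "-"
  compared <- sum(!both_gap)
  if (compared == 0L) abort("no comparable columns (all positions gapped in both rows)")
  sum(a == b & !both_gap) / compared
}

# internal: n x n pairwise identity matrix for an msa
identity_matrix <- function(x) {
  n <- nrow(x$seqs)
  gap <- x$seqs == "-"
  idm <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        both <- gap[i, ] & gap[j, ]
        compared <- sum(!both)
        idm[i, j] <- idm[j, i] <-
          if (compared == 0) 0 else sum(x$seqs[i, ] == x$seqs[j, ] & !both) / compared
      }
    }
  }
  idm
}

#' Effective number of sequences in an alignment
#'
#' Sequences more similar than an identity threshold are collapsed and
#' counted once: rows are single-linkage clustered on the pairwise-identity
#' graph (an edge wherever identity exceeds the threshold) and the
#' effective count Meff is the number of clusters. Equivalently each row
#' carries weight 1/(its cluster size); the weights, whose sum is Meff, are
#' attached as attribute `"weights"` for use in weighted column statistics.
#'
#' The default threshold is a fixed fractional identity of 0.62. A
#' `threshold_fun` hook taking the mean pairwise identity of the alignment
#' and returning a threshold can be supplied instead, for alignment-adaptive
#' schemes.
#'
#' @param x an [msa].
#' @param identity_threshold fractional identity in (0, 1); rows with
#'   pairwise identity above it collapse. Ignored when `threshold_fun` is
#'   given.
#' @param threshold_fun optional function `mean_identity -> threshold`.
#' @return Meff as a single number (cluster count), with attributes
#'   `"weights"` (per-row) and `"threshold"` (the value used).
#' @export
effective_sequences <- function(x, identity_threshold = 0.62,
                                threshold_fun = NULL) {
  stopifnot(inherits(x, "msa"))
  n <- nrow(x$seqs)
  idm <- identity_matrix(x)
  if (!is.null(threshold_fun)) {
    mean_id <- if (n > 1) mean(idm[upper.tri(idm)]) else 1
    identity_threshold <- threshold_fun(mean_id)
  }
  if (identity_threshold <= 0 || identity_threshold >= 1) {
    abort("identity_threshold must lie strictly between 0 and 1")
  }
  adj <- idm > identity_threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  w <- 1 / comp$csize[comp$membership]
  structure(comp$no, weights = as.numeric(w), threshold = identity_threshold)
}

#' Remove rows with too many gaps
#'
#' Drops alignment rows whose gap fraction exceeds `max_gap_fraction`
#' (default 20%). The query (first) row is always retained.
#'
#' @param x an [msa].
#' @param max_gap_fraction highest tolerated gap fraction per row.
#' @return The filtered [msa].
#' @export
filter_gappy_rows <- function(x, max_gap_fraction = 0.20) {
  stopifnot(inherits(x, "msa"))
  gap_frac <- rowMeans(x$seqs == "-")
  keep <- gap_frac <= max_gap_fraction
  keep[1] <- TRUE
  msa(x$seqs[keep, , drop = FALSE], ids = x$ids[keep])
}

#' Position-specific scoring matrix from an alignment
#'
#' For every alignment column and every state of the 21-letter alphabet the
#' profile value is the natural logarithm of the ratio of the (smoothed)
#' observed frequency to the background frequency. Smoothing mixes in
#' background-distributed pseudo-frequency mass:
#' `freq = (f_obs + pc * background) / (1 + pc)`, so the profile is exactly
#' zero wherever observed frequencies equal the background, and is invariant
#' under duplicating or permuting rows. Characters outside the alphabet
#' (e.g. `X`) are excluded from the counts.
#'
#' @param x an [msa].
#' @param background 21-vector of strictly positive reference frequencies
#'   summing to 1, ordered as [aa_alphabet]; default [default_background()].
#' @param pseudocount background-mixing weight `pc >= 0`; default 1.
#' @param weights optional per-row weights (e.g. from
#'   [effective_sequences()]); default unweighted.
#' @return An `ncol x 21` matrix of class `pssm` with the background stored
#'   as attribute `"background"`.
#' @export
compute_pssm <- function(x, background = default_background(),
                         pseudocount = 1, weights = NULL) {
  stopifnot(inherits(x, "msa"))
  if (length(background) != 21L) abort("background must have 21 entries")
  if (any(background <= 0)) abort("background frequencies must be strictly positive")
  if (abs(sum(background) - 1) > 1e-6) abort("background must sum to 1")
  n <- nrow(x$seqs)
  w <- weights %||% rep(1, n)
  if (length(w) != n) abort("one weight per row required")
  vals <- matrix(0, x$ncol, 21L,
                 dimnames = list(NULL, aa_alphabet))
  for (col in seq_len(x$ncol)) {
    st <- match(x$seqs[, col], aa_alphabet)
    ok <- !is.na(st)
    tot <- sum(w[ok])
    cnt <- numeric(21L)
    if (tot > 0) {
      agg <- rowsum(w[ok], st[ok])
      cnt[as.integer(rownames(agg))] <- agg[, 1]
      fobs <- cnt / tot
    } else {
      fobs <- background  # column of only unknown characters: uninformative
    }
    freq <- (fobs + pseudocount * background) / (1 + pseudocount)
    vals[col, ] <- log(freq / background)
  }
  structure(vals, background = background, class = c("pssm", "matrix", "array"))
}

#' Export a profile as a tibble
#'
#' @param x a `pssm` matrix from [compute_pssm()].
#' @param ... unused.
#' @return tibble with columns `position`, `state`, `value`.
#' @method tidy pssm
#' @export
tidy.pssm <- function(x, ...) {
  tibble::as_tibble(as.table(unclass(x)), .name_repair = "minimal") |>
    setNames(c("position", "state", "value")) |>
    dplyr::mutate(position = as.integer(factor(.data$position,
                                               levels = unique(.data$position))))
}
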