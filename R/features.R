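#' Feature configuration for pair encoding
#'
#' Fixes which ordinary features are encoded for a residue pair and the
#' geometry of the receptive field. The ordinary feature vector is the
#' ordered concatenation of: the k base-map scores at (i, j); the sequence
#' separation `j - i`; the profile rows of i and j (21 values each); the
#' secondary-structure probability window centred at i then at j (3 values
#' per residue); and the accessibility window centred at i then at j
#' (5 values per residue). Windows are zero-padded where they run past the
#' sequence ends. This order is frozen: serialised models depend on it.
#'
#' @param n_base_maps number k of base prediction maps.
#' @param use_separation,use_pssm,use_ss,use_rsa feature switches.
#' @param ss_window,rsa_window odd window widths (default 9, i.e. i-4..i+4).
#' @param field_halfwidth receptive-field halfwidth h >= 0; the field is a
#'   (2h+1) x (2h+1) square (default 5, an 11 x 11 field).
#' @param separation_transform optional function applied to `j - i` before
#'   encoding (identity by default).
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_base_maps, use_separation = TRUE,
                           use_pssm = TRUE, use_ss = TRUE, use_rsa = TRUE,
                           ss_window = 9L, rsa_window = 9L,
                           field_halfwidth = 5L,
                           separation_transform = NULL) {
  n_base_maps <- as.integer(n_base_maps)
  if (n_base_maps < 1) abort("at least one base map is required")
  if (ss_window %% 2 != 1 || rsa_window %% 2 != 1) {
    abort("ss_window and rsa_window must be odd")
  }
  if (field_halfwidth < 0) abort("field_halfwidth must be >= 0")
  structure(list(
    n_base_maps = n_base_maps,
    use_separation = isTRUE(use_separation), use_pssm = isTRUE(use_pssm),
    use_ss = isTRUE(use_ss), use_rsa = isTRUE(use_rsa),
    ss_window = as.integer(ss_window), rsa_window = as.integer(rsa_window),
    field_halfwidth = as.integer(field_halfwidth),
    separation_transform = separation_transform),
    class = "feature_config")
}

#' Length of the encoded feature vector
#'
#' @param config a [feature_config].
#' @param with_field include the flattened receptive field (layers > 0)?
#' @return integer vector length.
#' @export
feature_length <- function(config, with_field = FALSE) {
  stopifnot(inherits(config, "feature_config"))
  n <- config$n_base_maps +
    config$use_separation +
    config$use_pssm * 2L * 21L +
    config$use_ss * 2L * config$ss_window * 3L +
    config$use_rsa * 2L * config$rsa_window * 5L
  if (with_field) n <- n + (2L * config$field_halfwidth + 1L)^2L
  as.integer(n)
}

#' @export
print.feature_config <- function(x, ...) {
  cat(sprintf(
    "<feature_config> %d base maps | sep:%s pssm:%s ss:%s(w=%d) rsa:%s(w=%d) | field %dx%d\n  ordinary dim = %d, with field = %d\n",
    x$n_base_maps, x$use_separation, x$use_pssm, x$use_ss, x$ss_window,
    x$use_rsa, x$rsa_window, 2 * x$field_halfwidth + 1,
    2 * x$field_halfwidth + 1, feature_length(x), feature_length(x, TRUE)))
  invisible(x)
}

# internal: windowed per-residue features for many centres, zero-padded.
# tab: L x m table; centres: integer vector; window: odd width.
# Returns length(centres) x (window * m); per-position blocks of m values,
# positions ordered centre-window..centre+window.
window_block <- function(tab, centres, window) {
  L <- nrow(tab); m <- ncol(tab); h <- (window - 1L) %/% 2L
  out <- matrix(0, length(centres), window * m)
  for (o in seq_len(window)) {
    pos <- centres + (o - 1L - h)
    ok <- pos >= 1L & pos <= L
    if (any(ok)) {
      out[ok, ((o - 1L) * m + 1L):(o * m)] <- tab[pos[ok], , drop = FALSE]
    }
  }
  out
}

# internal: ordinary feature matrix for a set of pairs of one family.
# pairs: matrix with columns i, j (i < j).
encode_pairs <- function(family, pairs, config) {
  stopifnot(inherits(family, "contact_family"),
            inherits(config, "feature_config"))
  if (length(family$base_maps) != config$n_base_maps) {
    abort(sprintf("family has %d base maps, config expects %d",
                  length(family$base_maps), config$n_base_maps))
  }
  blocks <- list()
  ii <- pairs[, 1]; jj <- pairs[, 2]
  for (b in seq_len(config$n_base_maps)) {
    blocks[[length(blocks) + 1L]] <- family$base_maps[[b]]$scores[pairs]
  }
  if (config$use_separation) {
    sep <- jj - ii
    if (!is.null(config$separation_transform)) sep <- config$separation_transform(sep)
    blocks[[length(blocks) + 1L]] <- sep
  }
  if (config$use_pssm) {
    if (is.null(family$pssm)) abort(sprintf("family '%s' lacks a pssm table", family$id))
    blocks[[length(blocks) + 1L]] <- unclass(family$pssm)[ii, , drop = FALSE]
    blocks[[length(blocks) + 1L]] <- unclass(family$pssm)[jj, , drop = FALSE]
  }
  if (config$use_ss) {
    if (is.null(family$ss)) abort(sprintf("family '%s' lacks an ss table", family$id))
    blocks[[length(blocks) + 1L]] <- window_block(family$ss, ii, config$ss_window)
    blocks[[length(blocks) + 1L]] <- window_block(family$ss, jj, config$ss_window)
  }
  if (config$use_rsa) {
    if (is.null(family$rsa)) abort(sprintf("family '%s' lacks an rsa table", family$id))
    blocks[[length(blocks) + 1L]] <- window_block(family$rsa, ii, config$rsa_window)
    blocks[[length(blocks) + 1L]] <- window_block(family$rsa, jj, config$rsa_window)
  }
  x <- do.call(cbind, blocks)
  if (ncol(x) != feature_length(config)) {
    abort("internal error: feature dimension mismatch")  # nocov
  }
  if (any(!is.finite(x))) abort("non-finite value in encoded features")
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  x
}

#' Encode the ordinary feature vector of one residue pair
#'
#' See [feature_config()] for the frozen feature order. Per-residue tables
#' must cover all residues `1..L`; windows running past the chain ends are
#' zero-padded.
#'
#' @param family a [contact_family] carrying the base maps and per-residue
#'   tables required by `config`.
#' @param i,j 1-based residue indices with `i < j`.
#' @param config a [feature_config].
#' @return named numeric vector of length `feature_length(config)`.
#' @export
encode_pair <- function(family, i, j, config) {
  if (i >= j) abort("encode_pair requires i < j")
  if (i < 1 || j > family$length) abort("pair indices outside 1..L")
  drop(encode_pairs(family, cbind(i = i, j = j), config))
}

#' Extract the receptive field around a residue pair
#'
#' Returns the (2h+1) x (2h+1) block of a prediction map centred at
#' `(i, j)`: entry (a, b) is `map(i - h + a - 1, j - h + b - 1)`. Positions
#' outside the map are zero-padded, read as "no predicted contact".
#'
#' @param map a [prediction_map].
#' @param i,j centre pair (1-based).
#' @param halfwidth field halfwidth h >= 0.
#' @return numeric (2h+1) x (2h+1) matrix; the centre equals `map$scores[i, j]`.
#' @export
receptive_field <- function(map, i, j, halfwidth) {
  stopifnot(inherits(map, "prediction_map"))
  if (halfwidth < 0) abort("halfwidth must be >= 0")
  fl <- receptive_fields(map$scores, i, j, halfwidth)
  matrix(fl, 2 * halfwidth + 1, 2 * halfwidth + 1)
}

# internal, vectorised: fields for many centres as an n x (2h+1)^2 matrix.
# Flattening is column-major over the (row-offset, col-offset) square.
receptive_fields <- function(scores, ii, jj, h) {
  L <- nrow(scores)
  w <- 2L * h + 1L
  pad <- matrix(0, L + 2L * h, L + 2L * h)
  pad[(h + 1):(h + L), (h + 1):(h + L)] <- scores
  out <- matrix(0, length(ii), w * w)
  col <- 0L
  for (db in seq_len(w)) {
    for (da in seq_len(w)) {
      col <- col + 1L
      out[, col] <- pad[cbind(ii + da - 1L, jj + db - 1L)]
    }
  }
  out
}

#' Read per-residue feature tables
#'
#' `read_ss_table()` reads a TSV with columns `index, p_helix, p_strand,
#' p_coil`; `read_rsa_table()` one with `index, rsa, z_fit, p_helix,
#' p_strand, p_coil`. Rows must cover residues 1..L consecutively.
#'
#' @param path TSV file with a header line.
#' @return numeric matrix (L x 3 for SS, L x 5 for RSA) ordered by residue.
#' @export
read_ss_table <- function(path) {
  read_residue_table(path, 3L, "ss")
}

#' @rdname read_ss_table
#' @export
read_rsa_table <- function(path) {
  read_residue_table(path, 5L, "rsa")
}

read_residue_table <- function(path, m, what) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  df <- read.table(path, header = TRUE)
  if (ncol(df) != m + 1L) {
    abort(sprintf("%s table must have %d columns (index + %d values)", what, m + 1L, m))
  }
  df <- df[order(df[, 1]), , drop = FALSE]
  if (!identical(as.integer(df[, 1]), seq_len(nrow(df)))) {
    missing_at <- setdiff(seq_len(max(df[, 1])), df[, 1])
    abort(sprintf("%s table must cover residues 1..L; missing residue %s",
                  what, paste(head(missing_at, 3), collapse = ", ")))
  }
  as.matrix(df[, -1, drop = FALSE])
}
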