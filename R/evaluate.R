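#' Positive predictive value of the top-scoring pairs
#'
#' Ranks the unordered pairs with sequence separation at least `min_sep`
#' (and unmasked truth) by descending score and keeps the top
#' `ceiling(alpha * L)`; the PPV is the fraction of kept pairs that are
#' true contacts. Score ties are broken deterministically: larger
#' separation first, then smaller i, then smaller j. If fewer eligible
#' pairs exist than requested, all of them are used.
#'
#' @param pred a [prediction_map].
#' @param truth a [contact_map] of the same length.
#' @param alpha predictions per residue (default 1, the top-L protocol).
#' @param min_sep smallest separation evaluated (default 5).
#' @return PPV in `[0, 1]`.
#' @export
top_l_ppv <- function(pred, truth, alpha = 1, min_sep = 5L) {
  stopifnot(inherits(pred, "prediction_map"), inherits(truth, "contact_map"))
  if (pred$length != truth$length) abort("prediction and truth lengths differ")
  L <- truth$length
  idx <- eligible_pairs(L, min_sep, truth$mask)
  if (nrow(idx) == 0) abort("no eligible pairs at this separation/mask")
  sc <- pred$scores[idx]
  sep <- idx[, 2] - idx[, 1]
  ord <- order(-sc, -sep, idx[, 1], idx[, 2])
  n_take <- min(ceiling(alpha * L), nrow(idx))
  mean(truth$map[idx[ord[seq_len(n_take)], , drop = FALSE]])
}

#' PPV within sequence-separation ranges
#'
#' Pairs are partitioned by separation into short (6-12), medium (13-24)
#' and long (25+) ranges — boundary separations 12 and 24 belong to the
#' lower-labelled range — and the top `ceiling(L/10)` pairs *within each
#' range* are scored. A range with no eligible pairs is reported as `NA`,
#' not 0.
#'
#' @param pred a [prediction_map].
#' @param truth a [contact_map].
#' @param per_class_count predictions taken per range; default
#'   `ceiling(L / 10)`.
#' @param ranges named list of `c(lo, hi)` inclusive separation bounds.
#' @return tibble with one row per range: `range`, `n_eligible`, `n_taken`,
#'   `n_correct`, `ppv`.
#' @export
ppv_by_separation <- function(pred, truth, per_class_count = NULL,
                              ranges = list(short = c(6, 12),
                                            medium = c(13, 24),
                                            long = c(25, Inf))) {
  stopifnot(inherits(pred, "prediction_map"), inherits(truth, "contact_map"))
  if (pred$length != truth$length) abort("prediction and truth lengths differ")
  L <- truth$length
  n_take_max <- per_class_count %||% ceiling(L / 10)
  idx <- eligible_pairs(L, 1L, truth$mask)
  sep <- idx[, 2] - idx[, 1]
  purrr::imap(ranges, function(rg, nm) {
    in_rg <- sep >= rg[1] & sep <= rg[2]
    sub <- idx[in_rg, , drop = FALSE]
    if (nrow(sub) == 0) {
      return(tibble::tibble(range = nm, n_eligible = 0L, n_taken = 0L,
                            n_correct = 0L, ppv = NA_real_))
    }
    sc <- pred$scores[sub]
    ssep <- sub[, 2] - sub[, 1]
    ord <- order(-sc, -ssep, sub[, 1], sub[, 2])
    take <- ord[seq_len(min(n_take_max, nrow(sub)))]
    hits <- sum(truth$map[sub[take, , drop = FALSE]])
    tibble::tibble(range = nm, n_eligible = nrow(sub),
                   n_taken = length(take), n_correct = hits,
                   ppv = hits / length(take))
  }) |> dplyr::bind_rows()
}

#' PPV by secondary-structure category of the pair
#'
#' Takes the global top `ceiling(alpha * L)` pairs (as in [top_l_ppv()])
#' and assigns each to the unordered category of its two residues'
#' secondary-structure classes (helix H, strand E, loop C). Reports PPV
#' per category and the fraction of predictions falling in each category
#' (fractions sum to 1).
#'
#' @param pred a [prediction_map].
#' @param truth a [contact_map].
#' @param ss per-residue class labels in `H`/`E`/`C` covering all residues.
#' @param alpha,min_sep as in [top_l_ppv()].
#' @return tibble with one row per category: `category`, `n`, `n_correct`,
#'   `ppv` (`NA` for empty categories), `fraction`.
#' @export
ppv_by_ss_category <- function(pred, truth, ss, alpha = 1, min_sep = 5L) {
  stopifnot(inherits(pred, "prediction_map"), inherits(truth, "contact_map"))
  L <- truth$length
  ss <- as.character(ss)
  if (length(ss) != L) abort("ss must label every residue")
  if (!all(ss %in% c("H", "E", "C"))) {
    abort(sprintf("unknown secondary-structure symbol: %s",
                  paste(setdiff(unique(ss), c("H", "E", "C")), collapse = ", ")))
  }
  idx <- eligible_pairs(L, min_sep, truth$mask)
  if (nrow(idx) == 0) abort("no eligible pairs at this separation/mask")
  sc <- pred$scores[idx]
  sep <- idx[, 2] - idx[, 1]
  ord <- order(-sc, -sep, idx[, 1], idx[, 2])
  take <- idx[ord[seq_len(min(ceiling(alpha * L), nrow(idx)))], , drop = FALSE]
  nice <- c(H = "helix", E = "strand", C = "loop")
  cat_of <- function(a, b) {
    cl <- sort(factor(c(nice[a], nice[b]), levels = c("helix", "strand", "loop")))
    paste(cl, collapse = "-")
  }
  lv <- c("helix-helix", "helix-strand", "helix-loop",
          "strand-strand", "strand-loop", "loop-loop")
  cats <- factor(vapply(seq_len(nrow(take)),
                        function(r) cat_of(ss[take[r, 1]], ss[take[r, 2]]),
                        character(1)), levels = lv)
  hit <- truth$map[take]
  tibble::tibble(category = lv) |>
    dplyr::left_join(
      tibble::tibble(category = as.character(cats), hit = hit) |>
        dplyr::group_by(.data$category) |>
        dplyr::summarise(n = dplyr::n(), n_correct = sum(.data$hit)),
      by = "category") |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L),
                  n_correct = dplyr::coalesce(.data$n_correct, 0L),
                  ppv = ifelse(.data$n > 0, .data$n_correct / .data$n, NA_real_),
                  fraction = .data$n / sum(.data$n))
}

#' Neighbourhood statistics of contact maps
#'
#' For every position of a w x w window fully inside the map (centre off
#' the diagonal and, when the truth is masked, the window free of masked
#' pairs), counts the contacts among the w^2 - 1 neighbours of the centre
#' and accumulates two normalised histograms: one conditioned on the
#' centre being a contact, one on it being a non-contact. True contacts
#' cluster into secondary-structure patterns, so the contact-conditioned
#' histogram sits far to the right of the non-contact one.
#'
#' @param maps a [contact_map] or a list of them.
#' @param w odd window width (default 3).
#' @return tibble with columns `neighbours` (0 .. w^2 - 1), `centre`
#'   (`"contact"` / `"non_contact"`), `count` and `frequency` (normalised
#'   within each condition; `NA` when a condition has no cases).
#' @export
window_contact_statistics <- function(maps, w = 3L) {
  if (inherits(maps, "contact_map")) maps <- list(maps)
  if (w %% 2 != 1) abort("w must be odd")
  h <- (w - 1L) %/% 2L
  nmax <- w * w - 1L
  counts <- matrix(0, nmax + 1L, 2L,
                   dimnames = list(0:nmax, c("contact", "non_contact")))
  for (cm in maps) {
    stopifnot(inherits(cm, "contact_map"))
    L <- cm$length
    if (L < w) next
    m <- cm$map * 1
    # neighbour sums by summing the w^2 shifted copies of the interior
    inner <- (h + 1L):(L - h)
    acc <- matrix(0, length(inner), length(inner))
    for (da in -h:h) for (db in -h:h) {
      acc <- acc + m[inner + da, inner + db]
    }
    centre <- m[inner, inner]
    nb <- acc - centre
    ok <- outer(inner, inner, "!=")
    if (any(cm$mask & !diag(TRUE, L))) {
      # exclude windows touching masked pairs (the diagonal, masked by
      # construction, is tolerated)
      msk <- (cm$mask & !diag(TRUE, L)) * 1
      bad <- matrix(0, length(inner), length(inner))
      for (da in -h:h) for (db in -h:h) bad <- bad + msk[inner + da, inner + db]
      ok <- ok & (bad == 0)
    }
    for (state in 1:2) {
      sel <- ok & (centre == 2L - state)  # state 1: contact, 2: non-contact
      if (any(sel)) {
        tb <- tabulate(nb[sel] + 1L, nbins = nmax + 1L)
        counts[, state] <- counts[, state] + tb
      }
    }
  }
  tot <- colSums(counts)
  tibble::tibble(
    neighbours = rep(0:nmax, 2L),
    centre = rep(c("contact", "non_contact"), each = nmax + 1L),
    count = as.vector(counts),
    frequency = as.vector(cbind(
      if (tot[1] > 0) counts[, 1] / tot[1] else rep(NA_real_, nmax + 1L),
      if (tot[2] > 0) counts[, 2] / tot[2] else rep(NA_real_, nmax + 1L))))
}

#' Running-average PPV against effective alignment size
#'
#' Sorts per-family results by Meff and smooths the PPV with a centred
#' sliding window of `frame` families (truncated at the ends). With
#' `frame = 1` the curve is the sorted raw points; when `frame` exceeds
#' the number of families a single global mean is used for every point.
#'
#' @param results data frame with columns `meff` and `ppv`.
#' @param frame window size (default 20 families).
#' @return tibble sorted by `meff` with columns `meff`, `ppv`,
#'   `ppv_running`.
#' @export
ppv_vs_meff <- function(results, frame = 20L) {
  stopifnot(all(c("meff", "ppv") %in% names(results)), nrow(results) >= 1)
  df <- dplyr::arrange(tibble::as_tibble(results[, c("meff", "ppv")]), .data$meff)
  n <- nrow(df)
  if (frame > n) {
    df$ppv_running <- mean(df$ppv)
    return(df)
  }
  half_lo <- (frame - 1L) %/% 2L
  half_hi <- frame - 1L - half_lo
  df$ppv_running <- vapply(seq_len(n), function(k) {
    mean(df$ppv[max(1L, k - half_lo):min(n, k + half_hi)])
  }, numeric(1))
  df
}

#' Count isolated top-L predictions
#'
#' Takes the top `ceiling(alpha * L)` pairs of a prediction map (as in
#' [top_l_ppv()], no truth needed) and counts how many have no other
#' selected prediction inside the surrounding (2r+1) x (2r+1) window of
#' the symmetrised selection. Coevolution artefacts tend to be such
#' isolated spikes; the receptive field is designed to suppress them.
#'
#' @param pred a [prediction_map].
#' @param alpha,min_sep as in [top_l_ppv()].
#' @param radius neighbourhood radius r (default 1, a 3 x 3 window).
#' @return integer count, with the number of selected pairs as attribute
#'   `"n_top"`.
#' @export
count_isolated_predictions <- function(pred, alpha = 1, min_sep = 5L,
                                       radius = 1L) {
  stopifnot(inherits(pred, "prediction_map"))
  L <- pred$length
  idx <- eligible_pairs(L, min_sep)
  if (nrow(idx) == 0) abort("no eligible pairs at this separation")
  sc <- pred$scores[idx]
  sep <- idx[, 2] - idx[, 1]
  ord <- order(-sc, -sep, idx[, 1], idx[, 2])
  take <- idx[ord[seq_len(min(ceiling(alpha * L), nrow(idx)))], , drop = FALSE]
  sel <- matrix(0, L, L)
  sel[take] <- 1
  sel[take[, c(2, 1), drop = FALSE]] <- 1
  nb <- receptive_fields(sel, take[, 1], take[, 2], radius)
  centre_col <- (ncol(nb) + 1L) %/% 2L
  n_iso <- sum(rowSums(nb) - nb[, centre_col] == 0)
  structure(as.integer(n_iso), n_top = nrow(take))
}

#' Evaluate a trained stack on a set of families
#'
#' Predicts every family with every layer and tabulates the top-L PPV and
#' the isolated-prediction count per layer.
#'
#' @param stack a [contact_stack].
#' @param families list of [contact_family] objects with truth maps.
#' @param alpha predictions per residue.
#' @param min_sep minimum separation; defaults to the stack's configured
#'   training separation.
#' @return tibble with one row per family and layer: `family`, `meff`,
#'   `layer`, `ppv`, `n_isolated`, `n_top`.
#' @export
evaluate_stack <- function(stack, families, alpha = 1, min_sep = NULL) {
  stopifnot(inherits(stack, "contact_stack"))
  min_sep <- min_sep %||% stack$config$min_separation
  purrr::imap(families, function(f, k) {
    preds <- predict(stack, f)
    purrr::imap(preds, function(pm, nm) {
      iso <- count_isolated_predictions(pm, alpha = alpha, min_sep = min_sep)
      tibble::tibble(
        family = f$id, meff = f$meff,
        layer = as.integer(sub("layer_", "", nm)),
        ppv = top_l_ppv(pm, f$truth, alpha = alpha, min_sep = min_sep),
        n_isolated = as.integer(iso), n_top = attr(iso, "n_top"))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
}

#' Write an evaluation report to TSV and JSON
#'
#' @param report a data frame (e.g. from [evaluate_stack()]).
#' @param path output path without extension; `.tsv` and `.json` are
#'   appended.
#' @return invisible character vector of the two files written.
#' @export
write_eval_report <- function(report, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(report, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, json, digits = NA)
  invisible(c(tsv, json))
}
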