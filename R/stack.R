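#' Configuration of the layered stack
#'
#' The stack is a feed-forward cascade of learners. Layer 0 predicts every
#' eligible residue pair from the ordinary features alone; each subsequent
#' layer re-predicts the pair from the ordinary features concatenated with
#' the receptive field — the square of previous-layer contact probabilities
#' centred on the pair — so that clustered support (sheet ladders, helix
#' stripes) can promote a pair and isolated spikes are demoted.
#'
#' During training the receptive fields of layer t+1 are, by default, taken
#' from out-of-fold maps: the training families are split into `n_folds`
#' groups and each family's layer-t map is predicted by a model trained on
#' the other groups, so no layer consumes fields produced by a model that
#' saw the same pairs (`field_mode = "oof"`). `field_mode = "infold"`
#' reuses the single full-data model's own training predictions instead,
#' which is cheaper but lets optimism leak into the fields.
#'
#' @param feature_config a [feature_config].
#' @param n_layers number of layers (default 5).
#' @param learner a [learner_spec] (default: 100-tree random forest with
#'   minimum 500 samples per leaf).
#' @param min_separation pairs with `j - i` below this are excluded from
#'   training and predicted as 0 (default 5).
#' @param n_folds internal fold count for out-of-fold fields (default 3;
#'   folds are whole families).
#' @param field_mode `"oof"` or `"infold"`.
#' @param seed integer seed governing fold assignment and every learner fit.
#' @return An object of class `stack_config`.
#' @export
stack_config <- function(feature_config, n_layers = 5L,
                         learner = learner_spec(), min_separation = 5L,
                         n_folds = 3L, field_mode = c("oof", "infold"),
                         seed = 1L) {
  stopifnot(inherits(feature_config, "feature_config"),
            inherits(learner, "learner_spec"))
  field_mode <- match.arg(field_mode)
  if (n_layers < 1) abort("n_layers must be >= 1")
  if (n_folds < 2) abort("n_folds must be >= 2")
  structure(list(feature_config = feature_config,
                 n_layers = as.integer(n_layers), learner = learner,
                 min_separation = as.integer(min_separation),
                 n_folds = as.integer(n_folds), field_mode = field_mode,
                 seed = as.integer(seed)),
            class = "stack_config")
}

# internal: deterministic per-layer/per-fold learner seeds
layer_seed <- function(seed, layer, fold = 0L) {
  (seed + 7919L * layer + 104729L * fold) %% .Machine$integer.max
}

# internal: mirror per-pair predictions into a symmetric score matrix
scores_from_pairs <- function(p, pairs, L) {
  s <- matrix(0, L, L)
  s[pairs] <- p
  s[pairs[, c(2, 1), drop = FALSE]] <- p
  s
}

# internal: run code with a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Train a layered contact-prediction stack
#'
#' Pools the eligible pairs (`i < j`, separation at least
#' `config$min_separation`, truth unmasked) of all training families, fits
#' layer 0 on the ordinary features against the contact labels, then for
#' each further layer extracts receptive fields from the previous layer's
#' (out-of-fold) prediction maps and fits on the concatenation. Per-layer
#' mean top-L PPV on the training families is logged — both in-sample and,
#' for layers that produce fields, out-of-fold — and a warning is emitted
#' when the out-of-fold PPV drops from one layer to the next (a sign the
#' cascade is deep enough to start reconstructing secondary-structure
#' texture instead of refining contacts).
#'
#' @param families list of [contact_family] objects with `truth` maps.
#' @param config a [stack_config].
#' @param verbose print per-layer progress?
#' @return An object of class `contact_stack`: trained layers, the
#'   configuration, fold assignment, and a `history` tibble (one row per
#'   layer: `ppv_insample`, `ppv_oof`).
#' @export
train_stack <- function(families, config, verbose = FALSE) {
  stopifnot(inherits(config, "stack_config"))
  if (length(families) == 0) abort("at least one training family is required")
  fc <- config$feature_config
  for (f in families) {
    stopifnot(inherits(f, "contact_family"))
    if (is.null(f$truth)) abort(sprintf("family '%s' has no truth map", f$id))
    if (f$length < 2L * (2L * fc$field_halfwidth + 1L)) {
      warn(sprintf("family '%s' is shorter than twice the receptive field; padding will dominate",
                   f$id))
    }
  }
  n_fam <- length(families)
  pairs_list <- purrr::map(families, function(f) {
    eligible_pairs(f$length, config$min_separation, f$truth$mask)
  })
  if (any(vapply(pairs_list, nrow, integer(1)) == 0)) {
    abort("a family has no eligible pairs at this minimum separation")
  }
  ord_list <- purrr::map2(families, pairs_list,
                          function(f, p) encode_pairs(f, p, fc))
  y_list <- purrr::map2(families, pairs_list, function(f, p) f$truth$map[p])
  rows_per_fam <- vapply(pairs_list, nrow, integer(1))
  fam_of_row <- rep(seq_len(n_fam), rows_per_fam)
  row_split <- split(seq_along(fam_of_row), fam_of_row)
  ordinary <- do.call(rbind, ord_list)
  y <- as.integer(unlist(y_list))
  if (sum(y) == 0) abort("empty positive class: no contacts in the training labels")
  fold_of_fam <- with_seed(config$seed,
                           sample(rep_len(seq_len(config$n_folds), n_fam)))
  fold_of_row <- fold_of_fam[fam_of_row]

  h <- fc$field_halfwidth
  w2 <- (2L * h + 1L)^2L
  field_names <- paste0("g", seq_len(w2))
  lengths <- vapply(families, function(f) f$length, integer(1))

  maps_from_pred <- function(pred) {
    purrr::map(seq_len(n_fam), function(k) {
      scores_from_pairs(pred[row_split[[k]]], pairs_list[[k]], lengths[k])
    })
  }
  fields_from_maps <- function(maps) {
    blocks <- purrr::map(seq_len(n_fam), function(k) {
      receptive_fields(maps[[k]], pairs_list[[k]][, 1], pairs_list[[k]][, 2], h)
    })
    fl <- do.call(rbind, blocks)
    colnames(fl) <- field_names
    fl
  }
  mean_topl_ppv <- function(maps) {
    mean(purrr::map_dbl(seq_len(n_fam), function(k) {
      top_l_ppv(prediction_map(maps[[k]]), families[[k]]$truth,
                alpha = 1, min_sep = config$min_separation)
    }))
  }

  layers <- vector("list", config$n_layers)
  hist_in <- hist_oof <- rep(NA_real_, config$n_layers)
  prev_maps <- NULL
  for (t in seq_len(config$n_layers) - 1L) {
    x_t <- if (t == 0L) ordinary else cbind(ordinary, fields_from_maps(prev_maps))
    full_fit <- fit_learner(x_t, y, config$learner, layer_seed(config$seed, t))
    layers[[t + 1L]] <- full_fit
    pred_in <- predict_learner(full_fit, x_t)
    hist_in[t + 1L] <- mean_topl_ppv(maps_from_pred(pred_in))
    need_fields <- t < config$n_layers - 1L
    if (need_fields) {
      if (config$field_mode == "oof") {
        pred_oof <- numeric(length(y))
        for (fold in seq_len(config$n_folds)) {
          out_rows <- fold_of_row == fold
          fit_f <- fit_learner(x_t[!out_rows, , drop = FALSE], y[!out_rows],
                               config$learner, layer_seed(config$seed, t, fold))
          pred_oof[out_rows] <- predict_learner(fit_f, x_t[out_rows, , drop = FALSE])
        }
        hist_oof[t + 1L] <- mean_topl_ppv(maps_from_pred(pred_oof))
        prev_maps <- maps_from_pred(pred_oof)
      } else {
        hist_oof[t + 1L] <- hist_in[t + 1L]
        prev_maps <- maps_from_pred(pred_in)
      }
      if (t >= 1L && !is.na(hist_oof[t]) && hist_oof[t + 1L] < hist_oof[t]) {
        warn(sprintf(
          "validation PPV decreased from layer %d (%.3f) to layer %d (%.3f): the stack may be too deep",
          t - 1L, hist_oof[t], t, hist_oof[t + 1L]))
      }
    }
    if (verbose) {
      message(sprintf("layer %d: in-sample PPV %.3f%s", t, hist_in[t + 1L],
                      if (need_fields && config$field_mode == "oof")
                        sprintf(", out-of-fold PPV %.3f", hist_oof[t + 1L]) else ""))
    }
  }
  structure(list(
    layers = layers, config = config,
    fold_assignment = setNames(fold_of_fam,
                               vapply(families, function(f) f$id, character(1))),
    history = tibble::tibble(layer = seq_len(config$n_layers) - 1L,
                             ppv_insample = hist_in, ppv_oof = hist_oof),
    n_train_families = n_fam), class = "contact_stack")
}

#' Predict contact maps with a trained stack
#'
#' Runs the family through every layer: layer 0 scores the ordinary
#' features, each later layer scores the ordinary features plus the
#' receptive field read from the previous layer's map. Pairs below the
#' configured minimum separation (and the diagonal) are returned as 0.
#'
#' @param object a [contact_stack].
#' @param family a [contact_family] matching the stack's feature
#'   configuration (truth not required).
#' @param ... unused.
#' @return A list of [prediction_map] objects, one per layer
#'   (`layer_0 ... layer_D-1`); the last one is the stack's final output.
#' @export
predict.contact_stack <- function(object, family, ...) {
  stopifnot(inherits(family, "contact_family"))
  config <- object$config
  fc <- config$feature_config
  if (length(family$base_maps) != fc$n_base_maps) {
    abort(sprintf("family has %d base maps but the stack was trained with %d",
                  length(family$base_maps), fc$n_base_maps))
  }
  pairs <- eligible_pairs(family$length, config$min_separation)
  if (nrow(pairs) == 0) abort("family has no eligible pairs at this minimum separation")
  ordinary <- encode_pairs(family, pairs, fc)
  h <- fc$field_halfwidth
  out <- vector("list", config$n_layers)
  prev_scores <- NULL
  for (t in seq_len(config$n_layers) - 1L) {
    x_t <- if (t == 0L) {
      ordinary
    } else {
      fl <- receptive_fields(prev_scores, pairs[, 1], pairs[, 2], h)
      colnames(fl) <- paste0("g", seq_len(ncol(fl)))
      cbind(ordinary, fl)
    }
    p <- predict_learner(object$layers[[t + 1L]], x_t)
    prev_scores <- scores_from_pairs(p, pairs, family$length)
    out[[t + 1L]] <- prediction_map(prev_scores, method = sprintf("layer_%d", t))
  }
  names(out) <- sprintf("layer_%d", seq_len(config$n_layers) - 1L)
  out
}

#' @export
print.contact_stack <- function(x, ...) {
  fc <- x$config$feature_config
  cat(sprintf(
    "<contact_stack> %d layers | %s, %d trees, min leaf %d | field %dx%d | trained on %d families\n",
    x$config$n_layers, x$config$learner$backend, x$config$learner$n_trees,
    x$config$learner$min_leaf, 2 * fc$field_halfwidth + 1,
    2 * fc$field_halfwidth + 1, x$n_train_families))
  print(x$history)
  invisible(x)
}

#' Per-layer training history of a stack
#'
#' @param x a [contact_stack].
#' @param ... unused.
#' @return tibble with one row per layer: in-sample and out-of-fold mean
#'   top-L PPV on the training families.
#' @method tidy contact_stack
#' @export
tidy.contact_stack <- function(x, ...) x$history

#' One-row summary of a trained stack
#'
#' @param x a [contact_stack].
#' @param ... unused.
#' @return tibble with the architecture and training-set size.
#' @method glance contact_stack
#' @export
glance.contact_stack <- function(x, ...) {
  fc <- x$config$feature_config
  tibble::tibble(
    n_layers = x$config$n_layers, backend = x$config$learner$backend,
    n_trees = x$config$learner$n_trees, min_leaf = x$config$learner$min_leaf,
    field_halfwidth = fc$field_halfwidth,
    n_ordinary_features = feature_length(fc),
    n_train_families = x$n_train_families,
    final_ppv_insample = x$history$ppv_insample[x$config$n_layers])
}

stack_format_version <- "contactstack-archive-1"

#' Save and restore a trained stack
#'
#' `save_stack()` writes a single-file archive holding every layer model,
#' the full configuration, the training provenance, and a probe: the
#' final-layer predictions on a small deterministic synthetic family.
#' `load_stack()` refuses archives with a different format version,
#' re-predicts the probe family and errors unless the restored stack
#' reproduces the stored predictions bit for bit.
#'
#' @param stack a [contact_stack].
#' @param path archive file.
#' @return `save_stack()` returns `path` invisibly; `load_stack()` the
#'   restored [contact_stack].
#' @export
save_stack <- function(stack, path) {
  stopifnot(inherits(stack, "contact_stack"))
  probe_fam <- probe_family(stack$config)
  probe_pred <- predict(stack, probe_fam)
  probe <- probe_pred[[length(probe_pred)]]$scores
  archive <- list(format = stack_format_version,
                  package_version = as.character(utils::packageVersion("contactstack")),
                  stack = unclass(stack), probe = probe)
  saveRDS(archive, path)
  invisible(path)
}

#' @rdname save_stack
#' @export
load_stack <- function(path) {
  archive <- tryCatch(readRDS(path),
                      error = function(e) abort(sprintf(
                        "cannot read stack archive '%s': %s", path, conditionMessage(e))))
  if (!is.list(archive) || !identical(archive$format, stack_format_version)) {
    abort(sprintf("stack archive format mismatch: expected '%s'",
                  stack_format_version))
  }
  stack <- structure(archive$stack, class = "contact_stack")
  stack$config <- structure(stack$config, class = "stack_config")
  probe_fam <- probe_family(stack$config)
  probe_pred <- predict(stack, probe_fam)
  got <- probe_pred[[length(probe_pred)]]$scores
  if (!identical(got, archive$probe)) {
    abort("probe verification failed: restored stack does not reproduce stored predictions")
  }
  stack
}

# internal: small deterministic family used to verify archive integrity
probe_family <- function(config) {
  fc <- config$feature_config
  fams <- generate_dataset(n_families = 1, length_range = c(48L, 48L),
                           signal_range = c(1.2, 1.2),
                           k = fc$n_base_maps, seed = 424243L)
  fams[[1]]
}
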