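#' Specify the per-layer learner
#'
#' Every stack layer is a bagged-tree ensemble fit on labelled pair-feature
#' vectors that returns a contact probability. Two backends are provided:
#'
#' * `"rf_hist"` (default): a random forest with histogram-based split
#'   finding via xgboost in random-forest mode — one boosting round of
#'   `n_trees` parallel trees, per-tree row subsampling, per-node feature
#'   subsampling of `mtry` features, squared-error leaves (so each leaf
#'   stores the exact contact fraction of its samples and the ensemble
#'   prediction is a bagged class frequency in `[0, 1]`). Candidate splits
#'   are taken from `max_bin` feature quantiles, which makes single-CPU
#'   training of deep stacks practical; with leaves constrained to hold at
#'   least `min_leaf` samples the trees are shallow and insensitive to
#'   split resolution beyond this.
#' * `"rf_exact"`: a classical exact-split probability forest via ranger,
#'   for cross-checks and small problems.
#'
#' The tree count and leaf constraint default to 100 trees with at least
#' 500 samples per leaf — deliberately coarse leaves that regularise the
#' heavily unbalanced contact/non-contact problem.
#'
#' @param backend `"rf_hist"` or `"rf_exact"`.
#' @param n_trees trees per forest.
#' @param min_leaf minimum samples in any leaf.
#' @param mtry features tried per split; default `sqrt(p)` at fit time.
#' @param subsample per-tree row subsampling fraction (without
#'   replacement); default 0.632, the expected unique fraction of a
#'   bootstrap sample.
#' @param max_bin feature quantisation bins for `"rf_hist"`.
#' @return An object of class `learner_spec`.
#' @export
learner_spec <- function(backend = c("rf_hist", "rf_exact"), n_trees = 100L,
                         min_leaf = 500L, mtry = NULL, subsample = 0.632,
                         max_bin = 32L) {
  backend <- match.arg(backend)
  if (n_trees < 1 || min_leaf < 1) abort("n_trees and min_leaf must be >= 1")
  structure(list(backend = backend, n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf), mtry = mtry,
                 subsample = subsample, max_bin = as.integer(max_bin)),
            class = "learner_spec")
}

# internal: fit one layer learner. x: numeric matrix with colnames,
# y: 0/1 labels. Deterministic given seed.
fit_learner <- function(x, y, spec, seed) {
  stopifnot(inherits(spec, "learner_spec"))
  if (all(y == 0)) abort("empty positive class: no contacts in the training labels")
  mtry <- spec$mtry %||% max(1L, floor(sqrt(ncol(x))))
  if (spec$backend == "rf_hist") {
    dm <- xgboost::xgb.QuantileDMatrix(x, label = as.numeric(y),
                                       max_bin = spec$max_bin, nthread = 1)
    booster <- xgboost::xgb.train(
      params = list(
        tree_method = "hist", objective = "reg:squarederror",
        num_parallel_tree = spec$n_trees, subsample = spec$subsample,
        colsample_bynode = mtry / ncol(x), eta = 1, max_depth = 32,
        min_child_weight = spec$min_leaf, lambda = 0, alpha = 0,
        nthread = 1, seed = as.integer(seed), max_bin = spec$max_bin),
      data = dm, nrounds = 1, verbose = 0)
    model <- list(raw = xgboost::xgb.save.raw(booster))
  } else {
    fit <- ranger::ranger(x = x, y = factor(y, levels = c(0, 1)),
                          num.trees = spec$n_trees,
                          min.node.size = spec$min_leaf, mtry = mtry,
                          probability = TRUE, seed = as.integer(seed),
                          num.threads = 1)
    model <- list(ranger = fit)
  }
  structure(list(backend = spec$backend, model = model,
                 features = colnames(x), seed = as.integer(seed)),
            class = "layer_fit")
}

# internal: contact probabilities for a feature matrix, clamped to [0, 1]
predict_learner <- function(fit, x) {
  stopifnot(inherits(fit, "layer_fit"))
  if (!identical(colnames(x), fit$features)) {
    abort("feature columns do not match the fitted layer (dimension or order mismatch)")
  }
  p <- if (fit$backend == "rf_hist") {
    booster <- xgboost::xgb.load.raw(fit$model$raw)
    predict(booster, x)
  } else {
    predict(fit$model$ranger, data = x, num.threads = 1)$predictions[, "1"]
  }
  pmin(pmax(as.numeric(p), 0), 1)
}
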