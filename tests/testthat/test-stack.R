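test_that("a one-layer stack behaves exactly like a flat pair classifier", {
  fams <- tiny_dataset(6, seed = 50)
  cfg <- tiny_stack_config(n_layers = 1, seed = 19)
  st <- train_stack(fams, cfg)

  probe <- tiny_dataset(1, seed = 51)[[1]]
  got <- predict(st, probe)
  expect_length(got, 1)

  # reproduce by hand: pool ordinary features, fit the same learner with
  # the layer-0 seed, predict the probe's ordinary features
  fc <- cfg$feature_config
  xs <- lapply(fams, function(f) {
    p <- contactstack:::eligible_pairs(f$length, cfg$min_separation, f$truth$mask)
    contactstack:::encode_pairs(f, p, fc)
  })
  ys <- unlist(lapply(fams, function(f) {
    p <- contactstack:::eligible_pairs(f$length, cfg$min_separation, f$truth$mask)
    f$truth$map[p]
  }))
  flat <- contactstack:::fit_learner(do.call(rbind, xs), as.integer(ys),
                                     cfg$learner,
                                     contactstack:::layer_seed(cfg$seed, 0L))
  pp <- contactstack:::eligible_pairs(probe$length, cfg$min_separation)
  flat_pred <- contactstack:::predict_learner(
    flat, contactstack:::encode_pairs(probe, pp, fc))
  expect_equal(got[[1]]$scores[pp], flat_pred)
})

test_that("training and prediction are bit-reproducible under a fixed seed", {
  fams <- tiny_dataset(6, seed = 60)
  probe <- tiny_dataset(1, seed = 61)[[1]]
  cfg <- tiny_stack_config(n_layers = 2, seed = 23)
  p1 <- predict(train_stack(fams, cfg), probe)
  p2 <- predict(train_stack(fams, cfg), probe)
  expect_identical(lapply(p1, `[[`, "scores"), lapply(p2, `[[`, "scores"))

  cfg2 <- tiny_stack_config(n_layers = 2, seed = 24)
  p3 <- predict(train_stack(fams, cfg2), probe)
  expect_false(identical(p1[[2]]$scores, p3[[2]]$scores))
})

test_that("layer maps are probabilities, symmetric, and zero below the separation floor", {
  fams <- tiny_dataset(5, seed = 70)
  st <- train_stack(fams, tiny_stack_config(n_layers = 2, seed = 3))
  probe <- tiny_dataset(1, seed = 71)[[1]]
  for (pm in predict(st, probe)) {
    expect_true(all(pm$scores >= 0 & pm$scores <= 1))
    expect_identical(pm$scores, t(pm$scores))
    sep <- abs(row(pm$scores) - col(pm$scores))
    expect_true(all(pm$scores[sep < 5] == 0))
  }
  # training history was logged for every layer
  expect_equal(nrow(tidy(st)), 2)
  expect_true(all(tidy(st)$ppv_insample >= 0 & tidy(st)$ppv_insample <= 1))
  expect_equal(glance(st)$n_train_families, 5)
})

test_that("prediction of a family does not depend on others in the batch", {
  fams <- tiny_dataset(4, seed = 80)
  st <- train_stack(fams, tiny_stack_config(n_layers = 2, seed = 5))
  test_fams <- tiny_dataset(3, seed = 81)
  ev_fwd <- evaluate_stack(st, test_fams)
  ev_rev <- evaluate_stack(st, rev(test_fams))
  for (f in unique(ev_fwd$family)) {
    expect_equal(ev_fwd$ppv[ev_fwd$family == f],
                 ev_rev$ppv[ev_rev$family == f])
  }
})

test_that("training refuses label-free inputs", {
  fams <- tiny_dataset(3, seed = 90)
  # erase every contact: no positive class left
  for (q in seq_along(fams)) {
    fams[[q]]$truth <- contact_map(matrix(FALSE, fams[[q]]$length,
                                          fams[[q]]$length))
  }
  expect_error(train_stack(fams, tiny_stack_config(n_layers = 1)),
               "empty positive class")
  fam_nt <- tiny_dataset(1, seed = 91)[[1]]
  fam_nt$truth <- NULL
  expect_error(train_stack(list(fam_nt), tiny_stack_config()), "no truth")
})

test_that("stack archives round-trip exactly and refuse corrupt input", {
  fams <- tiny_dataset(5, seed = 95)
  st <- train_stack(fams, tiny_stack_config(n_layers = 2, seed = 31))
  probe <- tiny_dataset(1, seed = 96)[[1]]
  before <- predict(st, probe)

  path <- tempfile(fileext = ".rds")
  save_stack(st, path)
  st2 <- load_stack(path)
  after <- predict(st2, probe)
  expect_identical(lapply(before, `[[`, "scores"),
                   lapply(after, `[[`, "scores"))

  # truncated archive: hard error, no partial stack
  raw_bytes <- readBin(path, "raw", file.size(path))
  trunc_path <- tempfile(fileext = ".rds")
  writeBin(raw_bytes[1:floor(length(raw_bytes) / 2)], trunc_path)
  expect_error(load_stack(trunc_path), "cannot read")

  # format-version mismatch is detected before any use
  arch <- readRDS(path)
  arch$format <- "contactstack-archive-0"
  saveRDS(arch, trunc_path)
  expect_error(load_stack(trunc_path), "format mismatch")

  # probe verification notices tampered layer models
  arch <- readRDS(path)
  arch$probe <- arch$probe * 0.5
  saveRDS(arch, trunc_path)
  expect_error(load_stack(trunc_path), "probe")
})
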