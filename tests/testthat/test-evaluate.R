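random_instance <- function(L, seed, density = 0.08) {
  set.seed(seed)
  tm <- matrix(FALSE, L, L)
  tm[upper.tri(tm)] <- runif(sum(upper.tri(tm))) < density
  truth <- contact_map(tm)
  s <- matrix(0, L, L)
  s[upper.tri(s)] <- runif(sum(upper.tri(s)))
  list(truth = truth, pred = prediction_map(s + t(s)))
}

test_that("top-L PPV hits the closed-form corners", {
  L <- 30
  inst <- random_instance(L, 1, density = 0.3)
  perfect <- prediction_map(inst$truth$map * 1)
  n_true <- sum(inst$truth$map[eligible_pairs(L, 5)])
  expect_equal(top_l_ppv(perfect, inst$truth, alpha = n_true / L / 2), 1.0)

  empty <- contact_map(matrix(FALSE, L, L))
  expect_equal(top_l_ppv(inst$pred, empty, alpha = 1), 0.0)

  short <- random_instance(6, 2)
  expect_error(top_l_ppv(short$pred, short$truth, min_sep = 10), "eligible")
})

test_that("top-L PPV equals the exhaustive sort-and-count oracle", {
  for (seed in 1:20) {
    L <- sample(10:30, 1)
    inst <- random_instance(L, seed + 100, density = 0.15)
    for (alpha in c(0.5, 1, 2)) {
      expect_equal(
        top_l_ppv(inst$pred, inst$truth, alpha = alpha),
        oracle_top_l_ppv(inst$pred$scores, inst$truth$map, L, alpha, 5))
    }
  }
})

test_that("separation-range PPV follows Table-3-style per-class ranking", {
  L <- 30
  inst <- random_instance(L, 5, density = 0.3)
  perfect <- prediction_map(inst$truth$map * 1)
  tb <- ppv_by_separation(perfect, inst$truth)
  expect_true(all(tb$ppv[tb$n_eligible > 0] == 1))

  # contacts only at separation 30: short/medium ranges score no hits
  tm <- matrix(FALSE, 40, 40)
  tm[cbind(1:10, 31:40)] <- TRUE
  truth <- contact_map(tm)
  pred <- prediction_map(tm * 1)
  tb2 <- ppv_by_separation(pred, truth)
  expect_equal(tb2$ppv[tb2$range == "long"], 1)
  expect_true(all(tb2$n_correct[tb2$range != "long"] == 0))

  for (seed in 1:10) {
    L <- sample(15:30, 1)
    inst <- random_instance(L, seed + 300, density = 0.2)
    got <- ppv_by_separation(inst$pred, inst$truth)
    want <- oracle_ppv_by_separation(inst$pred$scores, inst$truth$map, L)
    expect_equal(setNames(got$ppv, got$range), want)
  }
})

test_that("ss-category PPV partitions the top-L predictions", {
  L <- 25
  inst <- random_instance(L, 9, density = 0.2)
  all_h <- rep("H", L)
  tb <- ppv_by_ss_category(inst$pred, inst$truth, all_h)
  expect_equal(tb$n[tb$category == "helix-helix"], 25)
  expect_true(all(tb$n[tb$category != "helix-helix"] == 0))
  expect_equal(sum(tb$fraction), 1)

  expect_error(ppv_by_ss_category(inst$pred, inst$truth, rep("X", L)),
               "unknown")

  for (seed in 1:10) {
    L <- sample(15:30, 1)
    inst <- random_instance(L, seed + 500, density = 0.2)
    ss <- sample(c("H", "E", "C"), L, replace = TRUE)
    got <- ppv_by_ss_category(inst$pred, inst$truth, ss)
    want <- oracle_ppv_by_ss(inst$pred$scores, inst$truth$map, L, ss)
    expect_equal(sum(got$fraction), 1)
    for (key in names(want)) {
      row <- got[got$category == key, ]
      expect_equal(row$n, unname(want[[key]]["n"]))
      expect_equal(row$n_correct, unname(want[[key]]["hit"]))
    }
  }
})

test_that("window statistics are normalised and match the exhaustive oracle", {
  empty <- contact_map(matrix(FALSE, 15, 15))
  ws <- window_contact_statistics(empty)
  nc <- ws[ws$centre == "non_contact", ]
  expect_equal(unname(nc$frequency[nc$neighbours == 0]), 1)
  expect_true(all(is.na(ws$frequency[ws$centre == "contact"])))

  set.seed(13)
  for (rep in 1:5) {
    tm <- matrix(FALSE, 20, 20)
    tm[upper.tri(tm)] <- runif(190) < 0.1
    cm <- contact_map(tm)
    ws <- window_contact_statistics(cm)
    want <- oracle_window_stats(list(cm$map))
    for (cond in c("contact", "non_contact")) {
      sub <- ws[ws$centre == cond, ]
      expect_equal(unname(sub$frequency[order(sub$neighbours)]),
                   unname(want[[cond]]))
      if (!all(is.na(sub$frequency))) expect_equal(sum(sub$frequency), 1)
    }
  }
})

test_that("the Meff running average degenerates correctly at the frame limits", {
  df <- data.frame(meff = c(30, 10, 20, 50, 40), ppv = c(0.5, 0.5, 0.5, 0.5, 0.5))
  out <- ppv_vs_meff(df, frame = 3)
  expect_equal(out$ppv_running, rep(0.5, 5))

  df2 <- data.frame(meff = c(3, 1, 2), ppv = c(0.9, 0.1, 0.5))
  out2 <- ppv_vs_meff(df2, frame = 1)
  expect_equal(out2$ppv_running, c(0.1, 0.5, 0.9))  # sorted raw points
  expect_equal(out2$meff, c(1, 2, 3))

  out3 <- ppv_vs_meff(df2, frame = 10)
  expect_equal(out3$ppv_running, rep(mean(df2$ppv), 3))

  set.seed(77)
  df4 <- data.frame(meff = sample(100, 30), ppv = runif(30))
  out4 <- ppv_vs_meff(df4, frame = 5)
  srt <- df4[order(df4$meff), ]
  for (k in 3:28) {
    expect_equal(out4$ppv_running[k], mean(srt$ppv[(k - 2):(k + 2)]))
  }
})

test_that("isolated predictions are counted against the symmetrised top set", {
  L <- 30
  s <- matrix(0, L, L)
  # a 3-cell cluster and two isolated spikes, all with separation >= 5
  s[5, 15] <- 0.9; s[6, 14] <- 0.8; s[5, 14] <- 0.85
  s[20, 28] <- 0.95
  s[2, 25] <- 0.7
  pm <- prediction_map(s + t(s))
  n_iso <- count_isolated_predictions(pm, alpha = 5 / L)
  expect_equal(as.integer(n_iso), 2)
  expect_equal(attr(n_iso, "n_top"), 5)
})
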