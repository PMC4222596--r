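test_that("generation is deterministic per seed and seeds decorrelate noise", {
  f1 <- generate_family(123, 60)
  f2 <- generate_family(123, 60)
  expect_identical(f1$truth$map, f2$truth$map)
  expect_identical(f1$base_maps[[1]]$scores, f2$base_maps[[1]]$scores)
  expect_identical(f1$pssm, f2$pssm)

  f3 <- generate_family(124, 60)
  expect_false(identical(f1$base_maps[[1]]$scores, f3$base_maps[[1]]$scores))

  d1 <- generate_dataset(3, seed = 9)
  d2 <- generate_dataset(3, seed = 9)
  expect_identical(purrr::map(d1, ~ .x$truth$map),
                   purrr::map(d2, ~ .x$truth$map))
})

test_that("all-coil chains have at most sparse long-range structure", {
  for (s in 1:5) {
    topo <- generate_topology(s, 80, composition = c(H = 0, E = 0, C = 1))
    expect_true(all(topo$ss_string == "C"))
    idx <- contactstack:::eligible_pairs(80, 5)
    expect_lt(sum(topo$truth$map[idx]), 0.15 * 80)
  }
})

test_that("strand-pair contacts form ladders: rungs continue diagonally", {
  n_checked <- 0
  for (s in 1:10) {
    topo <- generate_topology(s, 70, composition = c(H = 0, E = 0.6, C = 0.4))
    strand <- topo$ss_string == "E"
    m <- topo$truth$map
    idx <- which(m & upper.tri(m), arr.ind = TRUE)
    idx <- idx[(idx[, 2] - idx[, 1]) >= 5, , drop = FALSE]
    for (r in seq_len(nrow(idx))) {
      i <- idx[r, 1]; j <- idx[r, 2]
      if (!strand[i] || !strand[j]) next
      # interior rung of a ladder: a diagonal or anti-diagonal neighbour
      # within the strands continues the pattern
      nbrs <- rbind(c(i + 1, j - 1), c(i - 1, j + 1),
                    c(i + 1, j + 1), c(i - 1, j - 1))
      ok <- apply(nbrs, 1, function(p) {
        p[1] >= 1 && p[2] <= 70 && p[2] >= 1 && p[1] <= 70 && m[p[1], p[2]]
      })
      interior <- strand[max(i - 1, 1)] && strand[min(i + 1, 70)]
      if (interior) {
        expect_true(any(ok))
        n_checked <- n_checked + 1
      }
    }
  }
  expect_gt(n_checked, 50)
})

test_that("truth maps show the clustered-contact neighbourhood signature", {
  truths <- purrr::map(generate_dataset(12, seed = 31), "truth")
  ws <- window_contact_statistics(truths)
  mean_nb <- function(cond) {
    sub <- ws[ws$centre == cond, ]
    sum(sub$neighbours * sub$frequency)
  }
  expect_gt(mean_nb("contact"), mean_nb("non_contact"))
})

test_that("base-map quality is monotone in the signal parameter", {
  ppv_at <- function(signal) {
    mean(purrr::map_dbl(1:20, function(s) {
      topo <- generate_topology(s, 70)
      maps <- simulate_base_maps(topo$truth, k = 1, signal = signal, seed = s)
      top_l_ppv(maps[[1]], topo$truth)
    }))
  }
  p_low <- ppv_at(0.5); p_mid <- ppv_at(1.5); p_high <- ppv_at(3)
  expect_lt(p_low, p_mid)
  expect_lt(p_mid, p_high)
})

test_that("the noiseless and zero-signal limits bracket base-map quality", {
  dens <- numeric(0); chance <- numeric(0)
  for (s in 1:10) {
    topo <- generate_topology(s, 80)
    idx <- contactstack:::eligible_pairs(80, 5)
    # noiseless, artefact-free maps reproduce the truth ranking exactly
    clean <- simulate_base_maps(topo$truth, k = 1, signal = 5, fp_rate = 0,
                                isolated_fp_rate = 0, noise_sd = 0, seed = s)
    n_true <- sum(topo$truth$map[idx])
    expect_equal(top_l_ppv(clean[[1]], topo$truth, alpha = 0.9 * n_true / 80), 1.0)
    # zero signal: ranking is uninformative
    null <- simulate_base_maps(topo$truth, k = 1, signal = 0, seed = s)
    chance <- c(chance, top_l_ppv(null[[1]], topo$truth))
    dens <- c(dens, n_true / nrow(idx))
  }
  # mean chance-level PPV matches the analytic density within 2 SE
  se <- stats::sd(chance) / sqrt(length(chance))
  expect_lt(abs(mean(chance) - mean(dens)), 2 * se + 0.02)
})

test_that("simulated maps are symmetric, rectified, and reproducible", {
  topo <- generate_topology(7, 50)
  maps <- simulate_base_maps(topo$truth, k = 3, seed = 99)
  expect_length(maps, 3)
  for (m in maps) {
    expect_identical(m$scores, t(m$scores))
    expect_true(all(m$scores >= 0))
  }
  again <- simulate_base_maps(topo$truth, k = 3, seed = 99)
  expect_identical(maps[[2]]$scores, again[[2]]$scores)
  expect_false(identical(maps[[1]]$scores, maps[[2]]$scores))
})

test_that("families serialise to plain-text bundles that read back", {
  fam <- generate_family(55, 50, k = 2)
  dir <- tempfile()
  files <- write_family(fam, dir)
  expect_true(all(file.exists(files)))
  back <- read_rr(file.path(dir, "base_01.rr"), length = 50)
  # RR keeps strictly positive scores at 6-decimal precision
  pos <- fam$base_maps[[1]]$scores > 0
  expect_equal(back$scores[pos], fam$base_maps[[1]]$scores[pos],
               tolerance = 1e-5)
  ss_back <- read_ss_table(file.path(dir, "ss.tsv"))
  expect_equal(unname(ss_back), unname(fam$ss), tolerance = 1e-12)
})
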