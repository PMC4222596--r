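test_that("aligned FASTA and a3m parse to the same query coordinates", {
  f <- write_fasta(c("q", "s1"), c("ACDEF", "AC-EF"))
  m <- read_msa(f)
  expect_equal(m$ncol, 5)
  expect_equal(n_sequences(m), 2)
  expect_equal(paste(m$seqs[2, ], collapse = ""), "AC-EF")

  # five-row fixture: row-by-row equality
  rows <- c("ACDEF", "ACDEF", "AC-EF", "GHDEF", "AAAA-")
  f5 <- write_fasta(paste0("s", 1:5), rows)
  m5 <- read_msa(f5)
  for (r in 1:5) expect_equal(paste(m5$seqs[r, ], collapse = ""), rows[r])

  # a3m: lowercase insertions stripped
  fa3m <- tempfile(fileext = ".a3m")
  writeLines(c(">q", "ACDEF", ">h1", "ACdddDEF", ">h2", "A-DEf-"), fa3m)
  ma <- read_msa(fa3m)
  expect_equal(ma$ncol, 5)
  expect_equal(paste(ma$seqs[2, ], collapse = ""), "ACDEF")
  expect_equal(paste(ma$seqs[3, ], collapse = ""), "A-DE-")

  # ragged FASTA rejected
  fr <- write_fasta(c("a", "b"), c("ACDEF", "ACDE"))
  expect_error(read_msa(fr), "ragged")
})

test_that("pairwise identity follows the declared gap policy", {
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 1.0)
  expect_equal(pairwise_identity("AAAA", "CCCC"), 0.0)
  # hand count: A=A, C=C, D!=E, '-' vs G mismatch, F=F -> 3 of 5
  expect_equal(pairwise_identity("ACD-F", "ACEGF"), 3 / 5)
  # both-gap columns are skipped entirely
  expect_equal(pairwise_identity("A-C", "A-C"), 1.0)
  expect_error(pairwise_identity("--", "--"), "comparable")
  expect_error(pairwise_identity("AC", "ACD"), "equal")
})

test_that("effective sequence counts collapse near-identical rows", {
  m1 <- msa(rep("ACDEFGHIKL", 6))
  expect_equal(as.numeric(effective_sequences(m1)), 1)

  m2 <- msa(c("AAAAAAAAAA", "CCCCCCCCCC", "DDDDDDDDDD"))
  expect_equal(as.numeric(effective_sequences(m2)), 3)

  expect_error(effective_sequences(m1, identity_threshold = 1.2), "between 0 and 1")
  expect_error(effective_sequences(m1, identity_threshold = 0), "between 0 and 1")

  # weights always sum to Meff; threshold hook is honoured
  w <- attr(effective_sequences(m2), "weights")
  expect_equal(sum(w), 3)
  via_fun <- effective_sequences(m1, threshold_fun = function(mid) 0.5)
  expect_equal(attr(via_fun, "threshold"), 0.5)
})

test_that("effective sequences match a union-find single-linkage oracle", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(4:12, 1)
    base <- paste(sample(c("A", "C", "D", "E"), 20, replace = TRUE),
                  collapse = "")
    rows <- vapply(seq_len(n), function(r) {
      ch <- strsplit(base, "")[[1]]
      nmut <- sample(0:12, 1)
      pos <- sample(20, nmut)
      ch[pos] <- sample(c("A", "C", "D", "E", "-"), nmut, replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
    thr <- runif(1, 0.4, 0.9)
    got <- as.numeric(effective_sequences(msa(rows), identity_threshold = thr))
    expect_equal(got, oracle_meff(rows, thr))
  }
})

test_that("Meff is bounded and non-increasing as the threshold drops", {
  set.seed(3)
  for (rep in 1:5) {
    rows <- vapply(1:10, function(r) {
      paste(sample(c("A", "C", "D"), 15, replace = TRUE), collapse = "")
    }, character(1))
    m <- msa(rows)
    meffs <- vapply(c(0.9, 0.7, 0.5, 0.3), function(th) {
      as.numeric(effective_sequences(m, identity_threshold = th))
    }, numeric(1))
    expect_true(all(meffs >= 1 & meffs <= 10))
    expect_true(all(diff(meffs) <= 0))
  }
})

test_that("gappy rows are removed at the 20% default but the query survives", {
  gapless <- msa(c("ACDEF", "GHIKL"))
  expect_equal(n_sequences(filter_gappy_rows(gapless)), 2)

  row100 <- function(ngap) {
    paste(c(rep("-", ngap), rep("A", 100 - ngap)), collapse = "")
  }
  m <- msa(c(row100(0), row100(20), row100(21), row100(50)))
  kept <- filter_gappy_rows(m)
  expect_equal(kept$ids, c("seq_1", "seq_2"))  # 20% stays, 21% and 50% go

  gappy_query <- msa(c(row100(90), row100(0)))
  expect_equal(n_sequences(filter_gappy_rows(gappy_query)), 2)
})

test_that("profile values are zero at background and match hand computation", {
  # all 21 states once per column -> observed = uniform background -> zeros
  uniform_bg <- rep(1 / 21, 21)
  m <- msa(vapply(aa_alphabet, function(ch) paste(rep(ch, 3), collapse = ""),
                  character(1)))
  p <- compute_pssm(m, background = uniform_bg)
  expect_true(all(abs(p) < 1e-12))

  # single sequence "AAA", uniform background, pseudocount 1:
  # freq(A) = (1 + 1/21)/2, freq(other) = (1/21)/2
  p1 <- compute_pssm(msa("AAA"), background = uniform_bg, pseudocount = 1)
  expect_equal(unname(p1[1, "A"]), log(((1 + 1 / 21) / 2) / (1 / 21)))
  expect_equal(unname(p1[2, "C"]), log(0.5))
  expect_equal(nrow(p1), 3)
})

test_that("profiles are invariant under row duplication and permutation", {
  set.seed(5)
  rows <- vapply(1:6, function(r) {
    paste(sample(c("A", "C", "D", "-"), 12, replace = TRUE), collapse = "")
  }, character(1))
  p0 <- compute_pssm(msa(rows))
  expect_equal(compute_pssm(msa(c(rows, rows))), p0)
  expect_equal(compute_pssm(msa(rows[c(3, 1, 6, 2, 5, 4)])), p0)
})
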