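#' Generate a protein-like topology: secondary structure and true contacts
#'
#' Lays down helix/strand/coil segments along the chain and builds the
#' contact patterns those elements produce in real structures:
#'
#' * helices contribute local contacts at separations 3 and 4;
#' * strands are grouped into sheets of two or three and paired strands
#'   form hydrogen-bond ladders — anti-parallel ladders run along
#'   anti-diagonals (a contact at (i, j) implies one at (i+1, j-1)),
#'   parallel ladders along diagonals — widened by one cell to mimic
#'   side-chain packing, so sheet contacts come in dense blocks;
#' * paired helices contribute an intermittent anti-diagonal packing
#'   stripe: contact patches recur with the helical period rather than
#'   contiguously, so helix interfaces are markedly sparser and less
#'   regular than sheet ladders.
#'
#' Coil residues contribute no systematic contacts. Segment types are
#' drawn with probabilities proportional to the requested composition
#' (weighted by typical segment length), so the realised residue
#' composition approximates `composition`.
#'
#' @param seed integer seed; the topology is a deterministic function of it.
#' @param length chain length (at least 4).
#' @param composition named fractions for `H`, `E`, `C`, summing to 1.
#' @return list with `ss_string` (per-residue `H`/`E`/`C` vector) and
#'   `truth` (a [contact_map]).
#' @export
generate_topology <- function(seed, length,
                              composition = c(H = 0.35, E = 0.30, C = 0.35)) {
  if (length < 4) abort("length must be at least 4 (shortest segment)")
  composition <- composition[c("H", "E", "C")]
  if (any(is.na(composition)) || abs(sum(composition) - 1) > 1e-6) {
    abort("composition must be named fractions for H, E, C summing to 1")
  }
  with_seed(seed, {
    seg_len <- list(H = 8:14, E = 5:10, C = NULL)
    # elements alternate with coil linkers; element type drawn by residue
    # composition corrected for typical segment length, linker length chosen
    # so the realised coil fraction approximates the requested one
    elem_w <- composition[c("H", "E")] / c(H = 11, E = 7)
    mean_elem <- if (sum(elem_w) > 0) {
      sum(c(11, 7) * elem_w / sum(elem_w))
    } else 0
    mean_coil <- if (composition[["C"]] >= 0.999 || mean_elem == 0) {
      Inf
    } else {
      max(mean_elem * composition[["C"]] / (1 - composition[["C"]]), 0)
    }
    draw_coil_len <- function() {
      if (!is.finite(mean_coil)) return(length)
      if (mean_coil < 0.5) return(0L)
      lo <- max(1L, floor(0.6 * mean_coil))
      sample(lo:ceiling(1.5 * mean_coil), 1)
    }
    ss <- character(0)
    segs <- list()
    want_elem <- FALSE
    while (base::length(ss) < length) {
      if (want_elem && sum(elem_w) > 0) {
        ty <- sample(c("H", "E"), 1, prob = elem_w)
        ln <- sample(seg_len[[ty]], 1)
      } else {
        ty <- "C"
        ln <- max(draw_coil_len(), if (base::length(ss) == 0) 1L else 0L)
      }
      want_elem <- !want_elem
      if (ln == 0) next
      ln <- min(ln, length - base::length(ss))
      if (ln == 0) break
      start <- base::length(ss) + 1L
      ss <- c(ss, rep(ty, ln))
      segs[[base::length(segs) + 1L]] <- list(type = ty, from = start,
                                              to = start + ln - 1L)
    }
    map <- matrix(FALSE, length, length)
    put <- function(i, j) {
      ok <- i >= 1 & j >= 1 & i <= length & j <= length & i != j
      if (any(ok)) {
        map[cbind(i[ok], j[ok])] <<- TRUE
        map[cbind(j[ok], i[ok])] <<- TRUE
      }
    }
    helices <- purrr::keep(segs, ~ .x$type == "H" && (.x$to - .x$from + 1) >= 8)
    strands <- purrr::keep(segs, ~ .x$type == "E" && (.x$to - .x$from + 1) >= 4)
    # helix local contacts
    for (sg in purrr::keep(segs, ~ .x$type == "H")) {
      ii <- sg$from:sg$to
      put(ii, ii + 3L)
      put(ii, ii + 4L)
    }
    # sheets: group strands, ladder consecutive pairs
    if (base::length(strands) >= 2) {
      ord <- sample(base::length(strands))
      pos <- 1L
      while (pos < base::length(ord)) {
        size <- min(sample(2:4, 1), base::length(ord) - pos + 1L)
        sheet <- strands[ord[pos:(pos + size - 1L)]]
        pos <- pos + size
        for (q in seq_len(base::length(sheet) - 1L)) {
          s1 <- sheet[[q]]; s2 <- sheet[[q + 1L]]
          if (s1$from > s2$from) { tmp <- s1; s1 <- s2; s2 <- tmp }
          m <- min(s1$to - s1$from, s2$to - s2$from) + 1L
          anti <- runif(1) < 0.6
          t <- 0:(m - 1L)
          if (anti) {
            i <- s1$from + t; j <- s2$to - t
            put(i, j)          # rungs: (i, j) contact implies (i+1, j-1)
            put(i, j - 1L)     # Cbeta packing widens the ladder to a band
            put(i, j + 1L)
          } else {
            i <- s1$from + t; j <- s2$from + t
            put(i, j)
            put(i, j + 1L)
            put(i, j - 1L)
          }
        }
      }
    }
    # helix-helix packing stripes
    if (base::length(helices) >= 2) {
      ord <- sample(base::length(helices))
      for (q in seq(1, base::length(ord) - 1L, by = 2)) {
        if (runif(1) > 0.85) next
        h1 <- helices[[ord[q]]]; h2 <- helices[[ord[q + 1L]]]
        if (h1$from > h2$from) { tmp <- h1; h1 <- h2; h2 <- tmp }
        m <- min(h1$to - h1$from, h2$to - h2$from) + 1L
        # ridges-into-grooves: contact patches recur with helical period,
        # not contiguously along the interface
        t <- (0:(m - 1L))[(0:(m - 1L)) %% 4L < 2L]
        put(h1$from + t, h2$to - t)
        t2 <- t[t %% 4L == 0L]
        put(h1$from + t2, h2$to - t2 - 1L)
      }
    }
    # helix-strand packing: helices of alpha/beta folds lie across sheets
    if (base::length(helices) >= 1 && base::length(strands) >= 1) {
      for (hx in helices) {
        if (runif(1) > 0.5) next
        sx <- strands[[sample(base::length(strands), 1)]]
        a <- hx; b <- sx
        if (a$from > b$from) { tmp <- a; a <- b; b <- tmp }
        m <- min(a$to - a$from, b$to - b$from) + 1L
        t <- 0:(m - 1L)
        put(a$from + t, b$to - t)
        put(a$from + t, b$to - t + 1L)
      }
    }
    # sparse tertiary loop contacts: short clustered arcs anywhere
    n_arc <- rpois(1, length / 40)
    if (n_arc > 0 && length >= 14) {
      for (q in seq_len(n_arc)) {
        i0 <- sample(length - 10L, 1)
        j0 <- sample((i0 + 8L):min(length, i0 + 8L + length), 1)
        t <- 0:sample(1:2, 1)
        put(i0 + t, j0 - t)
      }
    }
    list(ss_string = ss, truth = contact_map(map))
  })
}

# internal: sample n non-contact pairs (sep >= min_sep) whose 3x3
# neighbourhood is contact-free and at least `gap` cells from already
# chosen positions, so they stay isolated
pick_isolated_sites <- function(n, truth, min_sep = 5L, gap = 2L) {
  if (n <= 0) return(matrix(integer(0), 0, 2))
  L <- truth$length
  idx <- eligible_pairs(L, min_sep)
  nb <- receptive_fields(truth$map * 1, idx[, 1], idx[, 2], 1L)
  free <- rowSums(nb) == 0
  cand <- idx[free, , drop = FALSE]
  if (nrow(cand) == 0) return(matrix(integer(0), 0, 2))
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  chosen <- matrix(integer(0), 0, 2)
  for (r in seq_len(nrow(cand))) {
    if (nrow(chosen) >= n) break
    if (nrow(chosen) == 0 ||
        all(pmax(abs(chosen[, 1] - cand[r, 1]),
                 abs(chosen[, 2] - cand[r, 2])) > gap)) {
      chosen <- rbind(chosen, cand[r, , drop = FALSE])
    }
  }
  chosen
}

#' Simulate noisy base prediction maps for a known truth
#'
#' Emulates the output of coevolution-based predictors: each of the k maps
#' scores every pair as `signal * truth + noise` (Gaussian, rectified at
#' zero) and is contaminated with false-positive peaks of two kinds —
#' clustered short ladders (plausible-looking artefacts) and isolated
#' single-cell spikes (the kind a receptive field can recognise and
#' remove). A configurable fraction of the false-positive sites is shared
#' across the k maps, mimicking systematic artefacts (e.g. phylogenetic
#' bias) that hit all coevolution methods alike and therefore survive
#' naive map averaging.
#'
#' @param truth a [contact_map].
#' @param k number of maps.
#' @param signal score amplitude on true contacts, in units of the noise
#'   standard deviation.
#' @param fp_rate expected clustered false-positive cells per residue.
#' @param isolated_fp_rate expected isolated false positives per residue.
#' @param shared_fraction fraction of false-positive sites common to all
#'   k maps.
#' @param noise_sd Gaussian noise standard deviation (0 gives noiseless
#'   maps).
#' @param seed integer seed.
#' @return list of k [prediction_map] objects.
#' @export
simulate_base_maps <- function(truth, k = 4L, signal = 1.2, fp_rate = 0.2,
                               isolated_fp_rate = 0.4, shared_fraction = 0.6,
                               noise_sd = 1, seed = 1L) {
  stopifnot(inherits(truth, "contact_map"))
  if (signal < 0) abort("signal must be >= 0")
  if (fp_rate < 0 || isolated_fp_rate < 0) abort("false-positive rates must be >= 0")
  L <- truth$length
  with_seed(seed, {
    up <- which(upper.tri(truth$map), arr.ind = TRUE)
    tm_up <- truth$map[up]
    amp <- function() signal * runif(1, 0.8, 1.3)
    draw_fp_sites <- function(rate_iso, rate_clu) {
      iso <- pick_isolated_sites(rpois(1, rate_iso * L), truth)
      sites <- list()
      if (nrow(iso) > 0) {
        sites <- purrr::map(seq_len(nrow(iso)),
                            ~ cbind(iso[.x, 1], iso[.x, 2]))
      }
      n_clu <- rpois(1, rate_clu * L / 3)
      cand <- eligible_pairs(L, 5L)
      for (q in seq_len(n_clu)) {
        a <- cand[sample(nrow(cand), 1), ]
        dirn <- if (runif(1) < 0.5) c(1, -1) else c(1, 1)
        t <- 0:2
        sites[[base::length(sites) + 1L]] <-
          cbind(a[1] + t * dirn[1], a[2] + t * dirn[2])
      }
      sites
    }
    shared_sites <- draw_fp_sites(shared_fraction * isolated_fp_rate,
                                  shared_fraction * fp_rate)
    shared_amp <- vapply(shared_sites, function(s) amp(), numeric(1))
    purrr::map(seq_len(k), function(m) {
      s_up <- signal * tm_up + rnorm(base::length(tm_up), sd = noise_sd)
      scores <- matrix(0, L, L)
      scores[up] <- s_up
      scores <- scores + t(scores)
      add_site <- function(cells, a) {
        cells <- cells[cells[, 1] >= 1 & cells[, 2] >= 1 &
                       cells[, 1] <= L & cells[, 2] <= L &
                       cells[, 1] != cells[, 2], , drop = FALSE]
        if (nrow(cells) > 0) {
          scores[cells] <<- a
          scores[cells[, c(2, 1), drop = FALSE]] <<- a
        }
      }
      for (q in seq_along(shared_sites)) {
        add_site(shared_sites[[q]], shared_amp[q] * runif(1, 0.9, 1.1))
      }
      own <- draw_fp_sites((1 - shared_fraction) * isolated_fp_rate,
                           (1 - shared_fraction) * fp_rate)
      for (cells in own) add_site(cells, amp())
      prediction_map(pmax(scores, 0), method = sprintf("sim_base_%d", m))
    })
  })
}

# internal: per-residue SS/RSA/profile surrogates whose informativeness
# grows with the family's signal strength (uninformative at signal 0)
surrogate_features <- function(ss_string, signal, seed) {
  L <- length(ss_string)
  fid <- signal / (signal + 1)
  cls <- match(ss_string, c("H", "E", "C"))
  with_seed(seed, {
    noisy_probs <- function() {
      t(vapply(seq_len(L), function(i) {
        u <- rexp(3); u <- u / sum(u)
        p <- (1 - fid) * u
        p[cls[i]] <- p[cls[i]] + fid
        p
      }, numeric(3)))
    }
    ss <- noisy_probs()
    rsa_mean <- c(0.40, 0.25, 0.60)[cls]
    rsa_val <- pmin(pmax(fid * rsa_mean + (1 - fid) * runif(L) +
                           rnorm(L, sd = 0.05), 0), 1)
    z_fit <- pmax(rnorm(L, mean = 1, sd = 0.4), 0)
    rsa <- cbind(rsa_val, z_fit, noisy_probs())
    templates <- matrix(-0.1, 3, 21,
                        dimnames = list(c("H", "E", "C"), aa_alphabet))
    templates["H", c("A", "E", "L", "M", "Q")] <- 0.6
    templates["E", c("V", "I", "Y", "W", "F", "T")] <- 0.6
    templates["C", c("G", "P", "N", "S", "D")] <- 0.6
    templates[, "-"] <- 0
    pssm <- fid * templates[cls, , drop = FALSE] +
      matrix(rnorm(L * 21, sd = 0.3), L, 21)
    list(ss = ss, rsa = rsa, pssm = pssm)
  })
}

#' Generate one synthetic protein family
#'
#' Combines [generate_topology()], [simulate_base_maps()] and surrogate
#' per-residue features into a ready-to-train [contact_family]. The Meff
#' surrogate is a lognormal draw whose scale grows with the signal
#' strength, mirroring the fact that larger effective alignments yield
#' stronger coevolution signal.
#'
#' @param seed integer seed (the family is a deterministic function of it).
#' @param length chain length.
#' @param signal base-map signal strength (see [simulate_base_maps()]).
#' @param composition secondary-structure composition for
#'   [generate_topology()].
#' @param k number of base maps.
#' @param fp_rate,isolated_fp_rate,shared_fraction,noise_sd passed to
#'   [simulate_base_maps()].
#' @return A [contact_family] with truth.
#' @export
generate_family <- function(seed, length = 80L, signal = 1.2,
                            composition = c(H = 0.35, E = 0.30, C = 0.35),
                            k = 4L, fp_rate = 0.2, isolated_fp_rate = 0.4,
                            shared_fraction = 0.6, noise_sd = 1) {
  topo <- generate_topology(seed, length, composition)
  maps <- simulate_base_maps(topo$truth, k = k, signal = signal,
                             fp_rate = fp_rate,
                             isolated_fp_rate = isolated_fp_rate,
                             shared_fraction = shared_fraction,
                             noise_sd = noise_sd, seed = seed + 1L)
  surr <- surrogate_features(topo$ss_string, signal, seed + 2L)
  meff <- with_seed(seed + 3L,
                    round(100 * (signal + 0.05)^2 * exp(rnorm(1, 0, 0.35))))
  contact_family(base_maps = maps, truth = topo$truth, pssm = surr$pssm,
                 ss = surr$ss, rsa = surr$rsa, ss_string = topo$ss_string,
                 meff = meff, id = sprintf("fam_%08d", seed))
}

#' Generate a synthetic family set
#'
#' Families vary in length, signal strength and (jittered) composition,
#' emulating the spread of family sizes and alignment depths seen across
#' real protein families. Deterministic per seed.
#'
#' @param n_families number of families (>= 1).
#' @param length_range inclusive range chain lengths are drawn from.
#' @param signal_range range the per-family signal is drawn from.
#' @param composition `NULL` (default mixed composition with per-family
#'   jitter) or a fixed named `H`/`E`/`C` vector used for every family.
#' @param k,fp_rate,isolated_fp_rate,shared_fraction,noise_sd passed to
#'   [generate_family()].
#' @param seed master seed.
#' @return list of [contact_family] objects.
#' @export
generate_dataset <- function(n_families = 20L, length_range = c(60L, 100L),
                             signal_range = c(0.8, 1.6), composition = NULL,
                             k = 4L, fp_rate = 0.2, isolated_fp_rate = 0.4,
                             shared_fraction = 0.6, noise_sd = 1, seed = 1L) {
  if (n_families < 1) abort("n_families must be >= 1")
  len_values <- length_range[1]:length_range[2]
  draws <- with_seed(seed, {
    list(seeds = sample.int(2^30, n_families),
         lens = len_values[sample.int(length(len_values), n_families,
                                      replace = TRUE)],
         signals = runif(n_families, signal_range[1], signal_range[2]),
         jitter = matrix(runif(3 * n_families, -0.06, 0.06), n_families, 3))
  })
  purrr::map(seq_len(n_families), function(q) {
    comp <- if (is.null(composition)) {
      cc <- pmax(c(H = 0.35, E = 0.30, C = 0.35) + draws$jitter[q, ], 0.02)
      cc / sum(cc)
    } else {
      composition[c("H", "E", "C")] / sum(composition)
    }
    generate_family(seed = draws$seeds[q], length = draws$lens[q],
                    signal = draws$signals[q], composition = comp, k = k,
                    fp_rate = fp_rate, isolated_fp_rate = isolated_fp_rate,
                    shared_fraction = shared_fraction, noise_sd = noise_sd)
  })
}

#' Write a synthetic family to plain-text files
#'
#' Writes the truth map and each base map as CASP RR files and the
#' per-residue tables as TSV, for interoperability with external tools.
#'
#' @param family a [contact_family].
#' @param dir output directory (created if needed).
#' @return invisible character vector of files written.
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "contact_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  if (!is.null(family$truth)) {
    p <- file.path(dir, "truth.rr")
    write_rr(prediction_map(family$truth$map * 1, method = "truth"), path = p)
    files <- c(files, p)
  }
  for (m in seq_along(family$base_maps)) {
    p <- file.path(dir, sprintf("base_%02d.rr", m))
    write_rr(family$base_maps[[m]], path = p)
    files <- c(files, p)
  }
  tabs <- list(ss = family$ss, rsa = family$rsa, pssm = family$pssm)
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    df <- data.frame(index = seq_len(family$length), unclass(tabs[[nm]]))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, p)
  }
  invisible(files)
}
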