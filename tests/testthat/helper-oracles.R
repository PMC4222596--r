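# Independent brute-force reference implementations used as oracles.
# These deliberately share no code with the package internals: plain loops
# and explicit sorting only.

oracle_contact_map <- function(coords, cutoff) {
  L <- nrow(coords)
  m <- matrix(FALSE, L, L)
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      if (i == j) next
      if (!coords$present[i] || !coords$present[j]) next
      d <- sqrt((coords$x[i] - coords$x[j])^2 +
                (coords$y[i] - coords$y[j])^2 +
                (coords$z[i] - coords$z[j])^2)
      m[i, j] <- d <= cutoff
    }
  }
  m
}

# explicit ranking with the documented tie-break (sep desc, i, j)
oracle_rank_pairs <- function(scores, L, min_sep, mask = NULL) {
  rows <- list()
  for (i in seq_len(L - 1)) {
    for (j in (i + 1):L) {
      if (j - i < min_sep) next
      if (!is.null(mask) && mask[i, j]) next
      rows[[length(rows) + 1]] <- data.frame(i = i, j = j,
                                             score = scores[i, j],
                                             sep = j - i)
    }
  }
  df <- do.call(rbind, rows)
  df[order(-df$score, -df$sep, df$i, df$j), ]
}

oracle_top_l_ppv <- function(scores, truth_map, L, alpha, min_sep,
                             mask = NULL) {
  df <- oracle_rank_pairs(scores, L, min_sep, mask)
  n_take <- min(ceiling(alpha * L), nrow(df))
  hits <- 0
  for (r in seq_len(n_take)) {
    if (truth_map[df$i[r], df$j[r]]) hits <- hits + 1
  }
  hits / n_take
}

oracle_ppv_by_separation <- function(scores, truth_map, L, mask = NULL) {
  n_take_max <- ceiling(L / 10)
  res <- list()
  for (rg in list(c("short", 6, 12), c("medium", 13, 24), c("long", 25, Inf))) {
    rows <- list()
    for (i in seq_len(L - 1)) {
      for (j in (i + 1):L) {
        sep <- j - i
        if (sep < as.numeric(rg[2]) || sep > as.numeric(rg[3])) next
        if (!is.null(mask) && mask[i, j]) next
        rows[[length(rows) + 1]] <- data.frame(i = i, j = j,
                                               score = scores[i, j], sep = sep)
      }
    }
    if (length(rows) == 0) {
      res[[rg[1]]] <- NA_real_
      next
    }
    df <- do.call(rbind, rows)
    df <- df[order(-df$score, -df$sep, df$i, df$j), ]
    n_take <- min(n_take_max, nrow(df))
    hits <- 0
    for (r in seq_len(n_take)) if (truth_map[df$i[r], df$j[r]]) hits <- hits + 1
    res[[rg[1]]] <- hits / n_take
  }
  unlist(res)
}

oracle_ppv_by_ss <- function(scores, truth_map, L, ss, alpha = 1,
                             min_sep = 5) {
  df <- oracle_rank_pairs(scores, L, min_sep)
  n_take <- min(ceiling(alpha * L), nrow(df))
  nice <- c(H = "helix", E = "strand", C = "loop")
  lvl <- c("helix", "strand", "loop")
  out <- list()
  for (r in seq_len(n_take)) {
    a <- nice[[ss[df$i[r]]]]; b <- nice[[ss[df$j[r]]]]
    pr <- sort(factor(c(a, b), levels = lvl))
    key <- paste(pr[1], pr[2], sep = "-")
    if (is.null(out[[key]])) out[[key]] <- c(n = 0, hit = 0)
    out[[key]]["n"] <- out[[key]]["n"] + 1
    out[[key]]["hit"] <- out[[key]]["hit"] + truth_map[df$i[r], df$j[r]]
  }
  out
}

oracle_window_stats <- function(maps, w = 3) {
  h <- (w - 1) / 2
  acc <- list(contact = integer(w * w), non_contact = integer(w * w))
  for (cm in maps) {
    L <- nrow(cm)
    for (i in (h + 1):(L - h)) {
      for (j in (h + 1):(L - h)) {
        if (i == j) next
        nb <- 0
        for (da in -h:h) for (db in -h:h) {
          if (da == 0 && db == 0) next
          if (cm[i + da, j + db]) nb <- nb + 1
        }
        key <- if (cm[i, j]) "contact" else "non_contact"
        acc[[key]][nb + 1] <- acc[[key]][nb + 1] + 1
      }
    }
  }
  lapply(acc, function(v) if (sum(v) > 0) v / sum(v) else rep(NA_real_, w * w))
}

# single-linkage clustering via hand-written union-find
oracle_meff <- function(rows, threshold) {
  n <- length(rows)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  ident <- function(a, b) {
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    both <- ca == "-" & cb == "-"
    if (sum(!both) == 0) return(0)
    sum(ca == cb & !both) / sum(!both)
  }
  for (a in seq_len(n - 1)) {
    for (b in (a + 1):n) {
      if (ident(rows[a], rows[b]) > threshold) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[ra] <- rb
      }
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

oracle_apc <- function(s) {
  L <- nrow(s)
  rm_ <- numeric(L)
  for (i in seq_len(L)) rm_[i] <- sum(s[i, -i]) / (L - 1)
  gm <- 0
  for (i in seq_len(L)) for (j in seq_len(L)) if (i != j) gm <- gm + s[i, j]
  gm <- gm / (L * (L - 1))
  out <- matrix(0, L, L)
  for (i in seq_len(L)) for (j in seq_len(L)) {
    if (i != j) out[i, j] <- s[i, j] - rm_[i] * rm_[j] / gm
  }
  out
}

# plug-in MI for one column pair at zero pseudocount
oracle_mi_pair <- function(a, b) {
  n <- length(a)
  tab <- table(a, b)
  p <- tab / n
  pa <- rowSums(p); pb <- colSums(p)
  s <- 0
  for (x in rownames(tab)) for (y in colnames(tab)) {
    if (p[x, y] > 0) s <- s + p[x, y] * log(p[x, y] / (pa[x] * pb[y]))
  }
  s
}

# index-by-index feature assembly for one pair, mirroring the documented
# frozen order but built independently
oracle_encode_pair <- function(family, i, j, k, ss_w = 9, rsa_w = 9) {
  v <- numeric(0)
  for (b in seq_len(k)) v <- c(v, family$base_maps[[b]]$scores[i, j])
  v <- c(v, j - i)
  v <- c(v, family$pssm[i, ], family$pssm[j, ])
  win <- function(tab, centre, w) {
    h <- (w - 1) / 2
    out <- numeric(0)
    for (pos in (centre - h):(centre + h)) {
      out <- c(out, if (pos >= 1 && pos <= nrow(tab)) tab[pos, ] else rep(0, ncol(tab)))
    }
    out
  }
  v <- c(v, win(family$ss, i, ss_w), win(family$ss, j, ss_w))
  v <- c(v, win(family$rsa, i, rsa_w), win(family$rsa, j, rsa_w))
  unname(v)
}
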