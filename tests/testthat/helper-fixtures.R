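# Small fixtures built in code.

# minimal but column-correct PDB ATOM records
pdb_atom_line <- function(serial, name, resid, chain, resno, x, y, z,
                          occ = 1.00, alt = " ", icode = " ", elem = "C") {
  name4 <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name4, alt, resid, chain, resno, icode, x, y, z, occ, 0, elem)
}

write_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

write_fasta <- function(ids, rows, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", ids), rows)), path)
  path
}

# tiny synthetic family with per-residue tables filled by formula, handy
# for exact feature-assembly checks
formula_family <- function(L = 20, k = 2, seed = 1) {
  set.seed(seed)
  maps <- lapply(seq_len(k), function(m) {
    s <- matrix(0, L, L)
    s[upper.tri(s)] <- runif(sum(upper.tri(s)))
    prediction_map(s + t(s), method = paste0("m", m))
  })
  truth <- matrix(FALSE, L, L)
  truth[cbind(1:(L - 6), 7:L)] <- TRUE
  contact_family(
    base_maps = maps,
    truth = contact_map(truth),
    pssm = matrix(rnorm(L * 21), L, 21),
    ss = matrix(runif(L * 3), L, 3),
    rsa = matrix(runif(L * 5), L, 5),
    ss_string = sample(c("H", "E", "C"), L, replace = TRUE),
    id = "formula")
}

# quick stack configuration for behavioural tests: tiny forests, narrow
# fields, leaves scaled to the small pair counts involved
tiny_stack_config <- function(k = 2, n_layers = 2, h = 2, seed = 11,
                              n_folds = 2, field_mode = "oof") {
  stack_config(
    feature_config(n_base_maps = k, field_halfwidth = h),
    n_layers = n_layers,
    learner = learner_spec(n_trees = 30, min_leaf = 60),
    n_folds = n_folds, field_mode = field_mode, seed = seed)
}

tiny_dataset <- function(n, seed, L = c(45, 60), ...) {
  generate_dataset(n, length_range = L, k = 2, seed = seed, ...)
}
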