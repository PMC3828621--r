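AA20 <- aa_alphabet()$letters

# Random pseudocounted frequency profile built from random counts.
random_pseudo_profile <- function(n_sites, n_seqs = 25L) {
  counts <- t(vapply(seq_len(n_sites), function(i) {
    p <- as.numeric(stats::rgamma(20, 0.5))
    as.integer(stats::rmultinom(1, n_seqs, p / sum(p)))
  }, integer(20)))
  colnames(counts) <- AA20
  rownames(counts) <- seq_len(n_sites)
  structure(counts, site_totals = rep(n_seqs, n_sites),
            excluded_positions = integer(0),
            class = c("count_matrix", class(counts)))
}

# Build an alignment whose column i consists of the letters in cols[[i]],
# one letter per sequence.
alignment_from_columns <- function(cols, ...) {
  n_seqs <- length(cols[[1L]])
  seqs <- vapply(seq_len(n_seqs), function(k)
    paste0(vapply(cols, `[`, character(1), k), collapse = ""), character(1))
  alignment(ids = paste0("s", seq_len(n_seqs)), seqs = seqs, ...)
}

# Classic fixed-column DSSP fixture.  `residues` is a data frame with
# columns chain, aa, acc; chain-break rows have aa == "!".
write_dssp_fixture <- function(path, residues) {
  header <- c(
    "==== Secondary Structure Definition by the program DSSP, CMBI version ==== DATE=2024-01-01        .",
    "REFERENCE W. KABSCH AND C.SANDER, BIOPOLYMERS 22 (1983) 2577-2637                                  .",
    "  1 CHAINS                                                                                          .",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA")
  lines <- character(nrow(residues))
  for (i in seq_len(nrow(residues))) {
    r <- residues[i, ]
    if (r$aa == "!") {
      lines[i] <- sprintf("%5d%5s   !", i, "")
    } else {
      lines[i] <- sprintf("%5d%5d %s %s%20s%4d", i, i, r$chain, r$aa, "", r$acc)
    }
  }
  writeLines(c(header, lines), path)
  path
}

# RSA profile fixture with explicit values.
rsa_fixture <- function(rsa, aa = NULL) {
  n <- length(rsa)
  if (is.null(aa)) aa <- rep("A", n)
  out <- data.frame(position = seq_len(n), aa = aa, asa = NA_real_, rsa = rsa)
  class(out) <- c("rsa_profile", "data.frame")
  out
}

# Generate a multi-protein benchmark in memory: per protein an RSA profile,
# a natural alignment (with ground truth) and designs across the spec's
# temperature sweep, all from per-protein seeds derived from the spec seed.
generate_protein_set <- function(spec, n_proteins) {
  out <- lapply(seq_len(n_proteins), function(p) {
    pseed <- (spec$seed + 10000L * p) %% 2147483629L
    rsa <- sample_rsa_profile(spec, seed = pseed)
    nat <- generate_natural_alignment(spec, rsa, seed = pseed)
    E <- draw_site_energies(spec, rsa, seed = pseed)
    designs <- lapply(spec$temperatures, function(T)
      generate_design_alignment(spec, rsa, T, E, seed = pseed)$alignment)
    names(designs) <- vapply(designs, `[[`, character(1), "condition")
    list(rsa = rsa, natural = nat, designs = designs, seed = pseed)
  })
  names(out) <- sprintf("protein_%02d", seq_len(n_proteins))
  out
}
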