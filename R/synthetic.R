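#' Specification for synthetic natural and designed alignments
#'
#' Defines the generative model used to exercise the whole pipeline without
#' external data.  Solvent exposure is drawn from a two-component Beta mixture
#' (one buried-enriched, one exposed-enriched component).  The natural model
#' draws each site's amino-acid distribution from a Dirichlet whose base
#' measure interpolates between a hydrophobic-favoring composition at low RSA
#' and a polar-favoring composition at high RSA, and whose concentration
#' `alpha(rsa) = alpha_min + alpha_range * rsa` increases with exposure — so
#' buried sites come out conserved and hydrophobic-enriched and exposed sites
#' variable and polar-enriched.  The design model gives each site a fixed
#' 20-vector of energies (`-log` of the site's base composition plus Gaussian
#' noise of sd `energy_sd`, drawn once per site and shared across
#' temperatures) and samples sequences from Boltzmann distributions
#' `p_j \propto exp(-E_j / T)` over the 19-letter design alphabet: cysteine
#' never occurs in designed sequences (its probability is exactly 0).
#'
#' @param n_sites Number of structure positions.
#' @param n_natural_seqs Natural sequences drawn per alignment.
#' @param n_design_seqs Designed sequences drawn per alignment (500 by
#'   default, matching typical design-set sizes).
#' @param temperatures Design temperature sweep (all > 0).
#' @param rsa_mix_weight Mixture weight of the buried-enriched component.
#' @param rsa_shape_buried,rsa_shape_exposed Beta shape pairs of the two
#'   mixture components.
#' @param alpha_min,alpha_range Dirichlet concentration at RSA 0 and its
#'   linear increase up to RSA 1 (both > 0).
#' @param energy_sd Standard deviation of the per-site energy noise.
#' @param base_buried,base_exposed Length-20 named compositions (sum to 1)
#'   used as Dirichlet base measures at RSA 0 and 1.
#' @param seed Integer seed; all sampling for a scenario flows from it via
#'   fixed sub-streams, never from the global RNG state.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_sites = 150L,
                           n_natural_seqs = 500L,
                           n_design_seqs = 500L,
                           temperatures = c(0.03, 0.1, 0.3, 0.6,
                                            0.9, 1.2, 1.8, 2.4),
                           rsa_mix_weight = 0.5,
                           rsa_shape_buried = c(0.9, 8),
                           rsa_shape_exposed = c(2.2, 1.8),
                           alpha_min = 0.2,
                           alpha_range = 5.5,
                           energy_sd = 1.0,
                           base_buried = NULL,
                           base_exposed = NULL,
                           seed = 1L) {
  ab <- aa_alphabet()
  if (is.null(base_buried))
    base_buried <- c(A = .10, C = .03, D = .015, E = .015, F = .08, G = .06,
                     H = .015, I = .12, K = .01, L = .15, M = .05, N = .02,
                     P = .02, Q = .015, R = .015, S = .04, T = .035, V = .13,
                     W = .03, Y = .05)
  if (is.null(base_exposed))
    base_exposed <- c(A = .06, C = .01, D = .08, E = .10, F = .02, G = .07,
                      H = .03, I = .03, K = .10, L = .05, M = .015, N = .06,
                      P = .055, Q = .06, R = .07, S = .06, T = .06, V = .04,
                      W = .01, Y = .02)
  check_base <- function(b, name) {
    if (!setequal(names(b), ab$letters) || length(b) != 20L)
      stop(sprintf("'%s' must be a named length-20 composition", name))
    b <- b[ab$letters]
    if (any(b < 0) || abs(sum(b) - 1) > 1e-9)
      stop(sprintf("'%s' must be nonnegative and sum to 1", name))
    b
  }
  base_buried <- check_base(base_buried, "base_buried")
  base_exposed <- check_base(base_exposed, "base_exposed")
  if (n_sites < 1L) stop("'n_sites' must be >= 1")
  if (n_natural_seqs < 2L || n_design_seqs < 2L)
    stop("sequence counts must be >= 2")
  if (length(temperatures) < 1L || any(temperatures <= 0))
    stop("'temperatures' must all be > 0")
  stopifnot_scalar_number(alpha_min, "alpha_min", positive = TRUE)
  stopifnot_scalar_number(alpha_range, "alpha_range")
  if (alpha_range < 0) stop("'alpha_range' must be >= 0")
  stopifnot_scalar_number(energy_sd, "energy_sd")
  if (energy_sd < 0) stop("'energy_sd' must be >= 0")
  if (rsa_mix_weight < 0 || rsa_mix_weight > 1)
    stop("'rsa_mix_weight' must be in [0, 1]")
  if (length(rsa_shape_buried) != 2L || any(rsa_shape_buried <= 0) ||
      length(rsa_shape_exposed) != 2L || any(rsa_shape_exposed <= 0))
    stop("Beta shape parameters must be pairs of positive numbers")
  structure(
    list(n_sites = as.integer(n_sites),
         n_natural_seqs = as.integer(n_natural_seqs),
         n_design_seqs = as.integer(n_design_seqs),
         temperatures = as.numeric(temperatures),
         rsa_mix_weight = rsa_mix_weight,
         rsa_shape_buried = as.numeric(rsa_shape_buried),
         rsa_shape_exposed = as.numeric(rsa_shape_exposed),
         alpha_min = alpha_min, alpha_range = alpha_range,
         energy_sd = energy_sd,
         base_buried = base_buried, base_exposed = base_exposed,
         seed = as.integer(seed)),
    class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("Synthetic alignment spec: %d sites, %d natural / %d designed seqs\n",
              x$n_sites, x$n_natural_seqs, x$n_design_seqs))
  cat("  temperatures:", paste(x$temperatures, collapse = ", "), "\n")
  cat(sprintf("  alpha(rsa) = %.3g + %.3g * rsa | energy sd %.3g | seed %d\n",
              x$alpha_min, x$alpha_range, x$energy_sd, x$seed))
  invisible(x)
}

# RSA-interpolated Dirichlet base composition (length-20, sums to 1).
base_mix <- function(spec, rsa) {
  w <- min(max(rsa, 0), 1)
  (1 - w) * spec$base_buried + w * spec$base_exposed
}

#' Sample a synthetic RSA profile
#'
#' Draws `n_sites` RSA values from the spec's two-component Beta mixture.
#' The residue letter at each site is the modal letter of the natural base
#' composition at that RSA.  Deterministic given `seed`.
#'
#' @param spec A [synthetic_spec()].
#' @param seed Seed; defaults to the spec's seed.
#' @return An `rsa_profile` with `position`, `aa`, `asa` (`NA`; no physical
#'   areas exist for synthetic sites) and `rsa`.
#' @export
sample_rsa_profile <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_sites
  rsa <- with_seed(child_seed(seed, 101L), {
    from_buried <- stats::runif(n) < spec$rsa_mix_weight
    ifelse(from_buried,
           stats::rbeta(n, spec$rsa_shape_buried[1L], spec$rsa_shape_buried[2L]),
           stats::rbeta(n, spec$rsa_shape_exposed[1L], spec$rsa_shape_exposed[2L]))
  })
  aa <- vapply(rsa, function(r) names(which.max(base_mix(spec, r))), character(1))
  out <- data.frame(position = seq_len(n), aa = aa, asa = NA_real_, rsa = rsa)
  class(out) <- c("rsa_profile", "data.frame")
  out
}

# Draw per-site natural distributions pi_i ~ Dirichlet(alpha(rsa) * base(rsa)).
natural_site_distributions <- function(spec, rsa_values) {
  probs <- t(vapply(rsa_values, function(r) {
    a <- (spec$alpha_min + spec$alpha_range * r) * base_mix(spec, r)
    g <- stats::rgamma(20L, shape = pmax(a, 1e-12))
    if (sum(g) == 0) g[which.max(a)] <- 1
    g / sum(g)
  }, numeric(20L)))
  colnames(probs) <- aa_alphabet()$letters
  probs
}

# Sample an alignment matrix (n_seqs x n_sites) from per-site distributions.
sample_alignment_matrix <- function(probs, n_seqs, letters20) {
  apply(probs, 1L, function(p) sample(letters20, n_seqs, replace = TRUE, prob = p))
}

finish_alignment <- function(probs, n_seqs, source_label, condition, seed_off,
                             seed) {
  letters20 <- aa_alphabet()$letters
  mat <- with_seed(child_seed(seed, seed_off),
                   sample_alignment_matrix(probs, n_seqs, letters20))
  ref <- letters20[apply(probs, 1L, which.max)]
  seqs <- c(paste0(ref, collapse = ""),
            apply(mat, 1L, paste0, collapse = ""))
  alignment(ids = c("ref", sprintf("seq_%04d", seq_len(n_seqs))),
            seqs = seqs, reference_id = "ref",
            source_label = source_label, condition = condition)
}

#' Generate a synthetic natural-like alignment
#'
#' Draws each site's amino-acid distribution from the spec's RSA-dependent
#' Dirichlet model, then samples `n_natural_seqs` residues i.i.d. per site.
#' The alignment is gapless; its first row (`"ref"`) is the per-site modal
#' sequence of the drawn distributions and serves as the reference row.
#'
#' @param spec A [synthetic_spec()].
#' @param rsa An `rsa_profile`, typically from [sample_rsa_profile()].
#' @param seed Seed; defaults to the spec's seed.
#' @return List with `alignment` (an `aa_alignment`, source `"natural"`) and
#'   `truth` (a `ground_truth` list with the per-site RSA values and true
#'   distributions, and the entropy-RSA correlation realized by those
#'   distributions).
#' @export
generate_natural_alignment <- function(spec, rsa, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(rsa, "rsa_profile"))
  if (nrow(rsa) != spec$n_sites)
    stop("RSA profile length does not match spec$n_sites")
  probs <- with_seed(child_seed(seed, 202L),
                     natural_site_distributions(spec, rsa$rsa))
  aln <- finish_alignment(probs, spec$n_natural_seqs, "natural", "natural",
                          303L, seed)
  H_true <- apply(probs, 1L, function(p) {
    p <- p[p > 0]; -sum(p * log(p))
  })
  truth <- structure(
    list(rsa = rsa$rsa, probs = probs, entropy = H_true,
         entropy_rsa_r = stats::cor(rsa$rsa, H_true)),
    class = "ground_truth")
  list(alignment = aln, truth = truth)
}

#' Draw per-site design energies
#'
#' One energy 20-vector per site: `-log` of the natural base composition at
#' the site's RSA (so designs share the natural model's hydrophobicity
#' structure), plus i.i.d. Gaussian noise of sd `energy_sd`.  Cysteine gets
#' infinite energy and therefore exactly zero probability at every
#' temperature.  Energies are a function of the seed only — not of the
#' temperature — so one draw is shared across a whole temperature sweep.
#'
#' @param spec A [synthetic_spec()].
#' @param rsa An `rsa_profile`.
#' @param seed Seed; defaults to the spec's seed.
#' @return Numeric matrix `n_sites` x 20 (column `C` is `Inf`).
#' @export
draw_site_energies <- function(spec, rsa, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(rsa, "rsa_profile"))
  letters20 <- aa_alphabet()$letters
  with_seed(child_seed(seed, 404L), {
    E <- t(vapply(rsa$rsa, function(r) {
      b <- base_mix(spec, r)
      b["C"] <- 0
      b <- b / sum(b)
      e <- ifelse(b > 0, -log(pmax(b, 1e-300)), Inf)
      e + stats::rnorm(20L, 0, spec$energy_sd)
    }, numeric(20L)))
    E[, letters20 == "C"] <- Inf
    colnames(E) <- letters20
    E
  })
}

#' Generate a synthetic designed-like alignment
#'
#' Samples `n_design_seqs` sequences from per-site Boltzmann distributions
#' `p_j \propto exp(-E_j / T)` over the 19-letter design alphabet (cysteine
#' probability exactly 0).  Lower temperatures concentrate each site on its
#' minimum-energy residue; higher temperatures approach the uniform
#' distribution over 19 letters, so mean entropy increases with `T`.
#'
#' @param spec A [synthetic_spec()].
#' @param rsa An `rsa_profile`.
#' @param temperature Design temperature (> 0).
#' @param energies Optional energy matrix from [draw_site_energies()]; by
#'   default drawn from the spec seed (hence shared across temperatures).
#' @param seed Seed; defaults to the spec's seed.
#' @return List with `alignment` (source `"designed"`, condition
#'   `"T<temperature>"`) and `truth` (per-site design distributions).
#' @export
generate_design_alignment <- function(spec, rsa, temperature,
                                      energies = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(rsa, "rsa_profile"))
  stopifnot_scalar_number(temperature, "temperature", positive = TRUE)
  if (is.null(energies)) energies <- draw_site_energies(spec, rsa, seed)
  probs <- t(apply(energies, 1L, function(e) {
    w <- exp(-(e - min(e)) / temperature)  # shift for numerical stability
    w[!is.finite(w)] <- 0
    w / sum(w)
  }))
  cond <- paste0("T", format(temperature, trim = TRUE))
  k <- which.min(abs(spec$temperatures - temperature))
  aln <- finish_alignment(probs, spec$n_design_seqs, "designed", cond,
                          505L + k, seed)
  truth <- structure(list(rsa = rsa$rsa, probs = probs, temperature = temperature),
                     class = "ground_truth")
  list(alignment = aln, truth = truth)
}

#' Write a complete synthetic benchmark scenario to disk
#'
#' Generates, for each of `n_proteins` synthetic proteins, an RSA table, a
#' natural alignment and one designed alignment per temperature in the spec's
#' sweep, writes everything as FASTA / TSV files plus a key-value manifest,
#' and returns the in-memory objects.  Re-running with the same spec and seed
#' reproduces identical files byte for byte.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @param n_proteins Number of synthetic proteins to generate.
#' @return Invisibly, a list with one element per protein: `rsa`, `natural`
#'   (list alignment/truth), `designs` (named list per temperature),
#'   `energies`, and `paths` of the written files.
#' @export
make_benchmark_scenario <- function(spec, dir, n_proteins = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", dir)
  manifest <- c(sprintf("seed\t%d", spec$seed),
                sprintf("n_proteins\t%d", n_proteins),
                sprintf("n_sites\t%d", spec$n_sites),
                sprintf("n_natural_seqs\t%d", spec$n_natural_seqs),
                sprintf("n_design_seqs\t%d", spec$n_design_seqs),
                sprintf("temperatures\t%s",
                        paste(spec$temperatures, collapse = ",")))
  out <- vector("list", n_proteins)
  names(out) <- sprintf("protein_%02d", seq_len(n_proteins))
  for (p in seq_len(n_proteins)) {
    pseed <- child_seed(spec$seed, 10000L * p)
    pdir <- file.path(dir, names(out)[p])
    dir.create(pdir, showWarnings = FALSE)
    rsa <- sample_rsa_profile(spec, seed = pseed)
    nat <- generate_natural_alignment(spec, rsa, seed = pseed)
    energies <- draw_site_energies(spec, rsa, seed = pseed)
    designs <- lapply(spec$temperatures, function(T)
      generate_design_alignment(spec, rsa, T, energies = energies, seed = pseed))
    names(designs) <- vapply(designs, function(d) d$alignment$condition,
                             character(1))
    paths <- c(rsa = file.path(pdir, "rsa.tsv"),
               natural = file.path(pdir, "natural.fasta"))
    write_rsa_table(rsa, paths[["rsa"]])
    write_alignment(nat$alignment, paths[["natural"]])
    for (cond in names(designs)) {
      fp <- file.path(pdir, paste0("design_", cond, ".fasta"))
      write_alignment(designs[[cond]]$alignment, fp)
      paths[[paste0("design_", cond)]] <- fp
    }
    truth_path <- file.path(pdir, "truth_entropy.tsv")
    utils::write.table(
      data.frame(position = seq_len(spec$n_sites), rsa = rsa$rsa,
                 entropy_true = nat$truth$entropy),
      truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[["truth"]] <- truth_path
    manifest <- c(manifest,
                  sprintf("%s\t%s", names(out)[p],
                          paste(basename(unlist(paths)), collapse = ",")))
    out[[p]] <- list(rsa = rsa, natural = nat, designs = designs,
                     energies = energies, paths = paths)
  }
  writeLines(manifest, file.path(dir, "manifest.tsv"))
  invisible(out)
}
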