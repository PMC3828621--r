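small_spec <- function(...) {
  synthetic_spec(n_sites = 40, n_natural_seqs = 30, n_design_seqs = 30,
                 temperatures = c(0.1, 0.6), seed = 9, ...)
}

test_that("generation is deterministic given the spec seed", {
  spec <- small_spec()
  r1 <- sample_rsa_profile(spec)
  r2 <- sample_rsa_profile(spec)
  expect_identical(r1, r2)
  n1 <- generate_natural_alignment(spec, r1)
  n2 <- generate_natural_alignment(spec, r1)
  expect_identical(n1$alignment$seqs, n2$alignment$seqs)
  expect_identical(n1$truth$probs, n2$truth$probs)
  d1 <- generate_design_alignment(spec, r1, 0.6)
  d2 <- generate_design_alignment(spec, r1, 0.6)
  expect_identical(d1$alignment$seqs, d2$alignment$seqs)
  # a different seed changes the draw
  expect_false(identical(
    generate_natural_alignment(spec, r1, seed = 10)$alignment$seqs,
    n1$alignment$seqs))
})

test_that("generators do not disturb the caller's RNG stream", {
  spec <- small_spec()
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(sample_rsa_profile(spec))
  invisible(generate_natural_alignment(spec, sample_rsa_profile(spec)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("designed alignments never contain cysteine; natural ones may", {
  spec <- small_spec()
  rsa <- sample_rsa_profile(spec)
  for (T in spec$temperatures) {
    d <- generate_design_alignment(spec, rsa, T)
    expect_identical(sum(strsplit(paste0(d$alignment$seqs, collapse = ""),
                                  "")[[1]] == "C"), 0L)
    expect_equal(unname(d$truth$probs[, "C"]), rep(0, spec$n_sites))
  }
  # the natural model gives cysteine positive probability
  nat <- generate_natural_alignment(spec, rsa)
  expect_true(all(nat$truth$probs[, "C"] >= 0))
})

test_that("ground-truth distributions are valid probability vectors", {
  spec <- small_spec()
  rsa <- sample_rsa_profile(spec)
  nat <- generate_natural_alignment(spec, rsa)
  expect_equal(rowSums(nat$truth$probs), rep(1, spec$n_sites),
               tolerance = 1e-12)
  expect_true(all(nat$truth$probs >= 0))
  des <- generate_design_alignment(spec, rsa, 0.3)
  expect_equal(rowSums(des$truth$probs), rep(1, spec$n_sites),
               tolerance = 1e-12)
})

test_that("design temperature limits behave as Boltzmann statistics dictate", {
  spec <- small_spec()
  rsa <- sample_rsa_profile(spec)
  E <- draw_site_energies(spec, rsa)
  # near-zero temperature: each site concentrates on its minimum-energy residue
  cold <- generate_design_alignment(spec, rsa, 0.01, E)
  H_cold <- apply(cold$truth$probs, 1, function(p) {
    p <- p[p > 0]; -sum(p * log(p)) })
  expect_lt(mean(H_cold), 0.05)
  # near-infinite temperature: uniform over the 19 design letters
  hot <- generate_design_alignment(spec, rsa, 1e6, E)
  non_c <- setdiff(AA20, "C")
  expect_true(all(abs(hot$truth$probs[, non_c] - 1 / 19) < 1e-3))
  H_hot <- apply(hot$truth$probs, 1, function(p) {
    p <- p[p > 0]; -sum(p * log(p)) })
  expect_equal(mean(H_hot), log(19), tolerance = 1e-3)
  expect_error(generate_design_alignment(spec, rsa, 0), "> 0")
  expect_error(generate_design_alignment(spec, rsa, -1), "> 0")
})

test_that("true design entropy increases monotonically with temperature", {
  spec <- synthetic_spec(n_sites = 80, n_natural_seqs = 30, n_design_seqs = 30,
                         seed = 4)
  rsa <- sample_rsa_profile(spec)
  E <- draw_site_energies(spec, rsa)
  mean_H <- vapply(spec$temperatures, function(T) {
    probs <- generate_design_alignment(spec, rsa, T, E)$truth$probs
    mean(apply(probs, 1, function(p) { p <- p[p > 0]; -sum(p * log(p)) }))
  }, numeric(1))
  expect_true(all(diff(mean_H) > 0))
})

test_that("a concentrated Dirichlet recovers the base-measure entropy", {
  # alpha -> infinity: drawn distributions converge on the base measure
  spec <- synthetic_spec(n_sites = 20, n_natural_seqs = 3000,
                         n_design_seqs = 10, alpha_min = 1e6, alpha_range = 0,
                         seed = 3)
  rsa <- sample_rsa_profile(spec)
  nat <- generate_natural_alignment(spec, rsa)
  base_H <- vapply(rsa$rsa, function(r) {
    b <- (1 - r) * spec$base_buried + r * spec$base_exposed
    -sum(b[b > 0] * log(b[b > 0]))
  }, numeric(1))
  counts <- column_counts(nat$alignment)
  emp_H <- site_entropy(site_frequencies(counts))
  expect_lt(max(abs(emp_H - base_H)), 0.05)
})

test_that("a flat natural model produces no entropy-RSA correlation", {
  uniform <- rep(1 / 20, 20); names(uniform) <- AA20
  spec <- synthetic_spec(n_sites = 500, n_natural_seqs = 30,
                         n_design_seqs = 10, alpha_min = 2, alpha_range = 0,
                         base_buried = uniform, base_exposed = uniform,
                         seed = 6)
  rsa <- sample_rsa_profile(spec)
  nat <- generate_natural_alignment(spec, rsa)
  r <- cor(rsa$rsa, nat$truth$entropy)
  expect_lt(abs(r), 0.1)
})

test_that("buried sites are hydrophobic-enriched relative to exposed sites", {
  spec <- synthetic_spec(n_sites = 200, n_natural_seqs = 60,
                         n_design_seqs = 10, seed = 11)
  rsa <- sample_rsa_profile(spec)
  nat <- generate_natural_alignment(spec, rsa)$alignment
  f <- class_aa_frequencies(list(nat), list(build_site_map(nat)), list(rsa))
  hyd <- c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
  expect_gt(sum(f["buried", hyd]), sum(f["exposed", hyd]))
})

test_that("the RSA mixture matches its component distribution", {
  spec <- synthetic_spec(n_sites = 10000, n_natural_seqs = 2,
                         n_design_seqs = 2, rsa_mix_weight = 1, seed = 2)
  rsa <- sample_rsa_profile(spec)
  expect_true(all(rsa$rsa >= 0 & rsa$rsa <= 1))
  expected <- pbeta(0.25, spec$rsa_shape_buried[1], spec$rsa_shape_buried[2])
  expect_equal(mean(rsa$rsa <= 0.25), expected, tolerance = 0.02)
})

test_that("spec validation rejects impossible parameters", {
  expect_error(synthetic_spec(n_sites = 0), "n_sites")
  expect_error(synthetic_spec(n_natural_seqs = 1), ">= 2")
  expect_error(synthetic_spec(temperatures = c(0.5, -1)), "> 0")
  expect_error(synthetic_spec(alpha_min = 0), "alpha_min")
  bad_base <- rep(0.06, 20); names(bad_base) <- AA20
  expect_error(synthetic_spec(base_buried = bad_base), "sum to 1")
})

test_that("benchmark scenarios round-trip through the file readers byte-identically", {
  spec <- synthetic_spec(n_sites = 25, n_natural_seqs = 12, n_design_seqs = 12,
                         temperatures = c(0.1, 1.2), seed = 14)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  sc1 <- make_benchmark_scenario(spec, d1, n_proteins = 2)
  sc2 <- make_benchmark_scenario(spec, d2, n_proteins = 2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_identical(f1, list.files(d2, recursive = TRUE))
  sums1 <- unname(tools::md5sum(file.path(d1, f1)))
  sums2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(sums1, sums2)
  # files load cleanly through the package's own readers
  expect_no_warning({
    aln <- read_alignment(sc1$protein_01$paths[["natural"]],
                          reference_id = "ref")
    rsa <- read_rsa_table(sc1$protein_01$paths[["rsa"]])
  })
  expect_identical(aln$seqs, sc1$protein_01$natural$alignment$seqs)
  expect_identical(nrow(rsa), spec$n_sites)
})
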