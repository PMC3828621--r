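test_that("pseudocounted frequencies follow the add-1/20 rule", {
  aln <- alignment_from_columns(list(c("A", "A", "A")))
  f <- site_frequencies(column_counts(aln), pseudocount = TRUE)
  expect_equal(unname(f[1, "A"]), 3.05 / 4)
  expect_equal(unname(f[1, "L"]), 0.05 / 4)
  expect_equal(sum(f[1, ]), 1, tolerance = 1e-12)
  expect_true(all(f > 0))

  # one of each amino acid: pseudocounting preserves the uniform distribution
  one_each <- alignment_from_columns(list(AA20))
  fu <- site_frequencies(column_counts(one_each), pseudocount = TRUE)
  expect_equal(unname(fu[1, ]), rep(0.05, 20), tolerance = 1e-12)

  # raw frequencies without pseudocount
  ls <- alignment_from_columns(list(rep("L", 10)))
  fr <- site_frequencies(column_counts(ls), pseudocount = FALSE)
  expect_identical(unname(fr[1, "L"]), 1)
  expect_identical(sum(fr[1, ] > 0), 1L)
})

test_that("site entropy matches its analytic values and bounds", {
  single <- alignment_from_columns(list(rep("W", 6)))
  expect_equal(unname(site_entropy(site_frequencies(column_counts(single)))),
               0)
  uniform <- alignment_from_columns(list(AA20))
  expect_equal(unname(site_entropy(site_frequencies(column_counts(uniform)))),
               log(20), tolerance = 1e-9)
  half <- alignment_from_columns(list(c("I", "I", "L", "L")))
  expect_equal(unname(site_entropy(site_frequencies(column_counts(half)))),
               log(2), tolerance = 1e-12)
})

test_that("entropy stays within [0, ln 20] on random profiles", {
  withr::local_seed(41)
  for (rep in 1:20) {
    prof <- random_pseudo_profile(30)
    H <- site_entropy(site_frequencies(prof))
    expect_true(all(H >= 0 & H <= log(20) + 1e-9))
    Hp <- site_entropy(site_frequencies(prof, pseudocount = TRUE))
    expect_true(all(Hp >= 0 & Hp <= log(20) + 1e-9))
  }
})

test_that("mean entropy and mean divergence are plain site averages", {
  expect_equal(mean_entropy(c(0, log(2))), log(2) / 2)
  expect_equal(mean_divergence(c(0.2, 0.4)), 0.3)
  expect_equal(mean_divergence(c(0, 0, 0)), 0)
  expect_error(mean_entropy(numeric(0)), "empty")
  expect_error(mean_divergence(numeric(0)), "empty")
  # brute-force check on a random profile
  withr::local_seed(7)
  prof <- site_frequencies(random_pseudo_profile(50))
  H <- site_entropy(prof)
  manual <- sum(vapply(seq_len(50), function(i) naive_entropy(prof[i, ]),
                       numeric(1))) / 50
  expect_equal(mean_entropy(H), manual, tolerance = 1e-12)
})

test_that("standard KL reproduces the independent per-site sum", {
  # natural counts {I:10, L:7, V:3} vs designed {A:10, V:7, I:3}, 20 seqs
  natural <- alignment_from_columns(list(c(rep("I", 10), rep("L", 7), rep("V", 3))))
  designed <- alignment_from_columns(list(c(rep("A", 10), rep("V", 7), rep("I", 3))))
  q <- site_frequencies(column_counts(natural), pseudocount = TRUE)
  p <- site_frequencies(column_counts(designed), pseudocount = TRUE)
  nat_counts <- integer(20); names(nat_counts) <- AA20
  nat_counts[c("I", "L", "V")] <- c(10L, 7L, 3L)
  des_counts <- integer(20); names(des_counts) <- AA20
  des_counts[c("A", "V", "I")] <- c(10L, 7L, 3L)
  expected <- naive_kl(naive_pseudo_freq(des_counts),
                       naive_pseudo_freq(nat_counts))
  expect_equal(unname(kl_divergence(p, q)[1]), expected, tolerance = 1e-12)
  expect_gt(expected, 0)
})

test_that("KL divergence is zero iff profiles are equal and never negative", {
  withr::local_seed(13)
  prof <- site_frequencies(random_pseudo_profile(40), pseudocount = TRUE)
  expect_equal(max(abs(kl_divergence(prof, prof))), 0, tolerance = 1e-12)
  for (rep in 1:10) {
    p <- site_frequencies(random_pseudo_profile(25), pseudocount = TRUE)
    q <- site_frequencies(random_pseudo_profile(25), pseudocount = TRUE)
    expect_true(all(kl_divergence(p, q) >= -1e-12))
    expect_true(all(rank_ordered_kl(p, q) >= -1e-12))
  }
})

test_that("KL requires strictly positive profiles", {
  raw <- site_frequencies(random_pseudo_profile(5), pseudocount = FALSE)
  pc <- site_frequencies(random_pseudo_profile(5), pseudocount = TRUE)
  expect_error(kl_divergence(pc, raw), "zero frequencies")
  expect_error(rank_ordered_kl(raw, pc), "zero frequencies")
})

test_that("KL divergence is not silently symmetrized", {
  withr::local_seed(99)
  p <- site_frequencies(random_pseudo_profile(20), pseudocount = TRUE)
  q <- site_frequencies(random_pseudo_profile(20), pseudocount = TRUE)
  expect_gt(max(abs(kl_divergence(p, q) - kl_divergence(q, p))), 1e-6)
})

test_that("rank-ordered KL of the equal-rank worked example is exactly zero", {
  # natural I/L/V at 0.5/0.35/0.15 vs designed A/V/I at the same frequencies:
  # identical sorted frequency vectors, so the rank comparison vanishes
  natural <- alignment_from_columns(list(c(rep("I", 10), rep("L", 7), rep("V", 3))))
  designed <- alignment_from_columns(list(c(rep("A", 10), rep("V", 7), rep("I", 3))))
  q <- site_frequencies(column_counts(natural), pseudocount = TRUE)
  p <- site_frequencies(column_counts(designed), pseudocount = TRUE)
  expect_identical(unname(rank_ordered_kl(p, q)[1]), 0)
  # while the standard KL at the same site is clearly positive
  expect_gt(kl_divergence(p, q)[1], 0.5)
})

test_that("both KL modes agree with the naive loop oracle on random profiles", {
  withr::local_seed(2024)
  for (rep in 1:8) {
    p <- site_frequencies(random_pseudo_profile(25), pseudocount = TRUE)
    q <- site_frequencies(random_pseudo_profile(25), pseudocount = TRUE)
    for (i in seq_len(25)) {
      expect_equal(unname(kl_divergence(p, q)[i]),
                   naive_kl(p[i, ], q[i, ]), tolerance = 1e-12)
      expect_equal(unname(rank_ordered_kl(p, q)[i]),
                   naive_rank_kl(p[i, ], q[i, ]), tolerance = 1e-12)
    }
  }
})

test_that("rank-ordered KL is invariant under independent relabelings, standard KL is not", {
  withr::local_seed(3)
  p <- site_frequencies(random_pseudo_profile(30), pseudocount = TRUE)
  q <- site_frequencies(random_pseudo_profile(30), pseudocount = TRUE)
  base_rank <- rank_ordered_kl(p, q)
  base_std <- kl_divergence(p, q)
  changed <- FALSE
  for (rep in 1:5) {
    perm_p <- sample(20); perm_q <- sample(20)
    pp <- p; pp[] <- unclass(p)[, perm_p]
    qq <- q; qq[] <- unclass(q)[, perm_q]
    expect_equal(unname(rank_ordered_kl(pp, qq)), unname(base_rank),
                 tolerance = 1e-12)
    if (max(abs(kl_divergence(pp, qq) - base_std)) > 1e-6) changed <- TRUE
  }
  expect_true(changed)
})

test_that("split-half control is zero for identical sequences and seed-deterministic", {
  ident <- alignment(paste0("s", 1:10), rep("ACDEFGHIKL", 10))
  expect_equal(split_half_control(ident, seed = 5), 0, tolerance = 1e-12)

  withr::local_seed(8)
  het <- alignment_from_columns(replicate(12, sample(AA20, 10, TRUE),
                                          simplify = FALSE))
  v1 <- split_half_control(het, seed = 42)
  v2 <- split_half_control(het, seed = 42)
  expect_identical(v1, v2)
  expect_gt(v1, 0)
  expect_error(split_half_control(alignment(c("a", "b", "c"),
                                            c("AC", "AC", "AC"))),
               "at least 4")
})
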