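test_that("entropy-RSA correlation matches analytic and oracle values", {
  rsa <- seq(0.05, 0.95, length.out = 10)
  up <- entropy_rsa_correlation(2 * rsa, rsa)
  expect_equal(up$r, 1.0, tolerance = 1e-12)
  up_s <- entropy_rsa_correlation(2 * rsa, rsa, method = "spearman")
  expect_equal(up_s$r, 1.0, tolerance = 1e-12)
  down <- entropy_rsa_correlation(-rsa, rsa)
  expect_equal(down$r, -1.0, tolerance = 1e-12)

  withr::local_seed(21)
  x <- runif(50); y <- runif(50)
  expect_equal(entropy_rsa_correlation(y, x)$r, naive_pearson(x, y),
               tolerance = 1e-12)
})

test_that("undefined correlations error instead of returning 0", {
  expect_error(entropy_rsa_correlation(c(1, 2, 3), rep(0.5, 3)), "constant")
  expect_error(entropy_rsa_correlation(rep(1, 5), runif(5)), "constant")
  expect_error(entropy_rsa_correlation(c(1, 2), c(0.1, 0.2)), "at least 3")
})

test_that("correlations are invariant under admissible RSA transforms", {
  withr::local_seed(33)
  for (rep in 1:5) {
    rsa <- runif(40); H <- runif(40)
    base_p <- entropy_rsa_correlation(H, rsa)$r
    base_s <- entropy_rsa_correlation(H, rsa, method = "spearman")$r
    # positive affine transform leaves pearson unchanged
    expect_equal(entropy_rsa_correlation(H, 3.2 * rsa + 0.7)$r, base_p,
                 tolerance = 1e-12)
    # strictly monotone transform leaves spearman unchanged
    expect_equal(entropy_rsa_correlation(H, exp(rsa), method = "spearman")$r,
                 base_s, tolerance = 1e-12)
  }
})

test_that("joining site statistics with RSA is lossless modulo logged exclusions", {
  map <- data.frame(column = 1:5, position = 1:5)
  class(map) <- c("site_map", "data.frame")
  rsa <- rsa_fixture(c(0.01, 0.1, 0.3, 0.6))  # position 5 missing
  expect_message(joined <- join_site_table(map, rsa), "excluded")
  expect_identical(nrow(joined), 4L)
  expect_identical(nrow(joined) + attr(joined, "n_excluded"), nrow(map))
  expect_identical(as.character(joined$exposure_class),
                   c("buried", "partially_buried", "exposed", "exposed"))
})

test_that("class entropy summaries reduce correctly for simple cases", {
  tab <- data.frame(
    exposure_class = factor(c("buried", "partially_buried", "exposed"),
                            levels = c("buried", "partially_buried", "exposed")),
    entropy_natural = c(0.1, 0.5, 1.2))
  res <- class_entropy_summary(list(p1 = tab))
  expect_equal(res$per_protein$mean_entropy, c(0.1, 0.5, 1.2))
  # single protein: the across-protein median equals the protein's own means
  expect_equal(sort(res$summary$median_entropy), c(0.1, 0.5, 1.2))
  # two proteins: medians are per-class medians across proteins
  tab2 <- tab; tab2$entropy_natural <- c(0.3, 0.7, 1.0)
  res2 <- class_entropy_summary(list(p1 = tab, p2 = tab2))
  buried <- res2$summary[res2$summary$exposure_class == "buried", ]
  expect_equal(buried$median_entropy, 0.2)
})

test_that("pooled class amino-acid frequencies follow the two-class split", {
  # one protein, one buried site, all sequences Leu
  aln <- alignment_from_columns(list(rep("L", 10)))
  map <- build_site_map(aln)
  rsa <- rsa_fixture(0.01)
  f <- class_aa_frequencies(list(aln), list(map), list(rsa))
  expect_equal(unname(f["buried", "L"]), 1.0)
  expect_true(all(is.na(f["exposed", ])))
  expect_identical(attr(f, "empty_classes"), "exposed")

  # pooling: two proteins each contributing one exposed Ala column
  a1 <- alignment_from_columns(list(rep("A", 10)))
  a2 <- alignment_from_columns(list(rep("A", 10)))
  r_exp <- rsa_fixture(0.5)
  f2 <- class_aa_frequencies(list(a1, a2), list(build_site_map(a1),
                                                build_site_map(a2)),
                             list(r_exp, r_exp))
  expect_equal(unname(f2["exposed", "A"]), 1.0)
  expect_equal(sum(f2["exposed", ]), 1, tolerance = 1e-9)

  expect_error(class_aa_frequencies(list(a1), list(map, map), list(rsa)),
               "same length")
  expect_error(class_aa_frequencies(list(a1), list(map), list(rsa),
                                    scheme = exposure_scheme("three_class")),
               "two-class")
})

test_that("non-empty class frequency vectors sum to one on mixed data", {
  withr::local_seed(12)
  aln <- alignment_from_columns(replicate(12, sample(AA20, 8, TRUE),
                                          simplify = FALSE))
  rsa <- rsa_fixture(runif(12))
  f <- class_aa_frequencies(list(aln), list(build_site_map(aln)), list(rsa))
  for (cl in rownames(f))
    if (!cl %in% attr(f, "empty_classes"))
      expect_equal(sum(f[cl, ]), 1, tolerance = 1e-9)
})

test_that("condition summaries use linear-interpolation quartiles", {
  df <- data.frame(condition = "A", mean_entropy = c(1, 2, 3, 4, 5))
  s <- summarize_conditions(df)
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$n, 5L)
  # a single value collapses all quartiles onto it
  s1 <- summarize_conditions(data.frame(condition = "B", cor_r = 0.37))
  expect_true(all(unlist(s1[, c("min", "q1", "median", "mean", "q3", "max")]) == 0.37))
})

test_that("paired condition test wraps a paired t-test", {
  withr::local_seed(5)
  x <- rnorm(12); y <- x + 0.5 + rnorm(12, sd = 0.1)
  res <- paired_condition_test(y, x)
  ref <- t.test(y, x, paired = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$estimate, unname(ref$estimate))
  expect_error(paired_condition_test(1, 2), "at least 2")
})
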