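# Independent reference implementations used as oracles.  These deliberately
# use explicit element-by-element loops and share no code with the package.

naive_entropy <- function(p) {
  p <- as.numeric(p)
  h <- 0
  for (j in seq_along(p)) if (p[j] > 0) h <- h - p[j] * log(p[j])
  h
}

naive_kl <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  d <- 0
  for (j in seq_along(p)) if (p[j] > 0) d <- d + p[j] * log(p[j] / q[j])
  d
}

naive_rank_kl <- function(p, q) {
  ps <- sort(p, decreasing = TRUE)
  qs <- sort(q, decreasing = TRUE)
  naive_kl(ps, qs)
}

naive_pearson <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Pseudocounted frequency row from a count vector, by the stated rule.
naive_pseudo_freq <- function(counts) (counts + 1 / 20) / (sum(counts) + 1)
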