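#' Per-site amino-acid frequency profile
#'
#' Converts per-site counts into per-site frequency distributions over the 20
#' canonical amino acids.  With `pseudocount = TRUE`, 1/20 is added to each of
#' the 20 amino-acid counts before normalizing (so the row denominator is the
#' site total plus one); this guarantees strictly positive frequencies and is
#' required for Kullback-Leibler comparisons.  Entropy calculations use raw
#' frequencies by default.
#'
#' @param counts A `count_matrix` from [column_counts()].
#' @param pseudocount Add 1/20 to every amino-acid count before normalizing?
#' @return A `freq_profile`: numeric matrix, rows summing to 1, with
#'   attribute `pseudocounted`.
#' @examples
#' aln <- alignment(c("r", "s", "t"), c("A", "A", "A"))
#' site_frequencies(column_counts(aln), pseudocount = TRUE)
#' @export
site_frequencies <- function(counts, pseudocount = FALSE) {
  stopifnot(inherits(counts, "count_matrix"))
  totals <- attr(counts, "site_totals")
  if (any(totals == 0L))
    stop("site with zero countable residues; exclude it before computing frequencies")
  m <- unclass(counts)
  attr(m, "site_totals") <- NULL
  attr(m, "excluded_positions") <- NULL
  storage.mode(m) <- "double"
  freqs <- if (pseudocount) (m + 1 / 20) / (totals + 1) else m / totals
  structure(freqs, pseudocounted = isTRUE(pseudocount),
            class = c("freq_profile", class(freqs)))
}

#' @export
print.freq_profile <- function(x, ...) {
  cat(sprintf("Frequency profile: %d sites x 20 letters (%s)\n", nrow(x),
              if (attr(x, "pseudocounted")) "pseudocounted" else "raw"))
  invisible(x)
}

#' Per-site Shannon entropy
#'
#' Site entropy \eqn{H_i = -\sum_j p_{ij} \ln p_{ij}} in nats, with the
#' convention \eqn{0 \ln 0 = 0}.  Higher values mean more variable sites;
#' the maximum over 20 amino acids is \eqn{\ln 20 \approx 2.996}.
#'
#' @param freqs A `freq_profile`.
#' @return Numeric vector of per-site entropies (named by structure position).
#' @examples
#' aln <- alignment(c("r", "s"), c("IL", "LL"))
#' site_entropy(site_frequencies(column_counts(aln)))
#' @export
site_entropy <- function(freqs) {
  stopifnot(inherits(freqs, "freq_profile"))
  p <- unclass(freqs)
  terms <- ifelse(p > 0, p * log(p), 0)
  h <- -rowSums(terms)
  # clamp tiny negative round-off
  h[h < 0 & h > -1e-12] <- 0
  names(h) <- rownames(freqs)
  h
}

#' Mean entropy of an alignment
#'
#' Arithmetic mean of per-site entropies; the paper-style summary of the
#' overall variability of one alignment.
#'
#' @param H Numeric vector of per-site entropies.
#' @return Single number (nats).
#' @export
mean_entropy <- function(H) {
  if (length(H) == 0L) stop("empty entropy vector")
  mean(H)
}

# shared validation for the two KL modes
check_kl_inputs <- function(p, q) {
  stopifnot(inherits(p, "freq_profile"), inherits(q, "freq_profile"))
  if (!identical(dim(p), dim(q)))
    stop("focal and reference profiles must have identical dimensions")
  if (any(unclass(q) <= 0))
    stop("reference profile contains zero frequencies; use pseudocounted profiles")
  if (any(unclass(p) <= 0))
    stop("focal profile contains zero frequencies; use pseudocounted profiles")
}

#' Per-site Kullback-Leibler divergence
#'
#' Standard per-site KL divergence
#' \eqn{D_i = \sum_j p_{ij} \ln(p_{ij}/q_{ij})} (nats) of a focal profile
#' `p` (conventionally the designed alignment) against a reference profile
#' `q` (conventionally the natural alignment).  Both profiles must be
#' pseudocounted so that all frequencies are strictly positive.  KL divergence
#' is asymmetric: swapping `p` and `q` generally changes the value.
#'
#' @param p Focal `freq_profile` (pseudocounted).
#' @param q Reference `freq_profile` (pseudocounted), same dimensions.
#' @return Numeric vector of per-site divergences with attribute
#'   `mode = "standard"`.
#' @seealso [rank_ordered_kl()], [mean_divergence()]
#' @export
kl_divergence <- function(p, q) {
  check_kl_inputs(p, q)
  pm <- unclass(p); qm <- unclass(q)
  d <- rowSums(pm * log(pm / qm))
  d[d < 0 & d > -1e-12] <- 0
  names(d) <- rownames(pm)
  attr(d, "mode") <- "standard"
  d
}

#' Rank-ordered Kullback-Leibler divergence
#'
#' KL divergence of frequency-rank distributions: at each site both 20-vectors
#' are sorted in descending order and compared rank against rank, so the
#' statistic measures only the *shape* of the amino-acid distribution,
#' ignoring which specific amino acids carry the frequencies.  Two sites
#' using entirely different amino acids at identical sorted frequencies have
#' rank-ordered divergence zero.
#'
#' @inheritParams kl_divergence
#' @return Numeric vector of per-site divergences with attribute
#'   `mode = "rank_ordered"`.
#' @export
rank_ordered_kl <- function(p, q) {
  check_kl_inputs(p, q)
  pm <- t(apply(unclass(p), 1L, sort, decreasing = TRUE))
  qm <- t(apply(unclass(q), 1L, sort, decreasing = TRUE))
  d <- rowSums(pm * log(pm / qm))
  d[d < 0 & d > -1e-12] <- 0
  names(d) <- rownames(unclass(p))
  attr(d, "mode") <- "rank_ordered"
  d
}

#' Mean per-protein divergence
#'
#' Averages per-site KL divergences over all sites of a protein, yielding the
#' protein-level divergence summary.
#'
#' @param div Numeric vector of per-site divergences.
#' @return Single number (nats).
#' @export
mean_divergence <- function(div) {
  if (length(div) == 0L) stop("empty divergence vector")
  mean(div)
}

#' Split-half natural-vs-natural control
#'
#' Baseline for how large a KL divergence to expect between two alignments
#' drawn from the same underlying site distributions: the natural alignment is
#' randomly split into two halves (sizes floor(n/2) and ceiling(n/2)) and the
#' mean standard KL of the first half (focal) against the second (reference)
#' is returned, both halves pseudocounted.  With `reps > 1` the value is
#' averaged over independent random splits.  Deterministic given `seed`.
#'
#' @param natural An `aa_alignment` with at least 4 records.
#' @param map Optional `site_map`; defaults to the map of `natural`.
#' @param seed Integer seed controlling the random split(s).
#' @param reps Number of independent splits to average over.
#' @param alphabet An [aa_alphabet()].
#' @return Mean control KL divergence (single number).
#' @export
split_half_control <- function(natural, map = NULL, seed = 1L, reps = 1L,
                               alphabet = aa_alphabet()) {
  stopifnot(inherits(natural, "aa_alignment"))
  n <- length(natural$ids)
  if (n < 4L) stop("split-half control needs at least 4 records")
  if (is.null(map)) map <- build_site_map(natural, alphabet)
  vals <- vapply(seq_len(reps), function(r) {
    perm <- with_seed(child_seed(seed, r - 1L), sample.int(n))
    ia <- perm[seq_len(n %/% 2L)]
    ib <- perm[(n %/% 2L + 1L):n]
    half <- function(idx) {
      a <- natural
      a$ids <- natural$ids[idx]
      a$seqs <- natural$seqs[idx]
      a$reference_id <- a$ids[1L]
      suppressWarnings(
        site_frequencies(column_counts(a, map, alphabet), pseudocount = TRUE))
    }
    pa <- half(ia)
    pb <- half(ib)
    if (!identical(dim(pa), dim(pb)))
      stop("halves cover different site sets; alignment too gappy for control")
    mean_divergence(kl_divergence(pa, pb))
  }, numeric(1))
  mean(vals)
}
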