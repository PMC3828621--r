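#' Join per-site statistics with solvent accessibility
#'
#' Inner join of mapped structure positions with an RSA profile.  Positions
#' present in only one of the two sides are excluded and counted in the
#' `n_excluded` attribute (with a message), so joining is lossless modulo
#' logged exclusions.
#'
#' @param map A `site_map`.
#' @param rsa An `rsa_profile` with RSA values filled.
#' @param scheme An [exposure_scheme()] used to add an `exposure_class`
#'   column.
#' @return Data frame with columns `position`, `column`, `rsa`,
#'   `exposure_class`; attribute `n_excluded`.
#' @export
join_site_table <- function(map, rsa, scheme = exposure_scheme()) {
  stopifnot(inherits(rsa, "rsa_profile"))
  if (anyNA(rsa$rsa)) stop("RSA values not computed; run compute_rsa() first")
  common <- intersect(map$position, rsa$position)
  n_excluded <- (nrow(map) - length(common)) +
    (nrow(rsa) - length(common))
  if (n_excluded > 0L)
    message(sprintf("join_site_table: %d position(s) present on one side only were excluded",
                    n_excluded))
  idx_map <- match(common, map$position)
  idx_rsa <- match(common, rsa$position)
  out <- data.frame(position = common,
                    column = map$column[idx_map],
                    rsa = rsa$rsa[idx_rsa])
  out$exposure_class <- classify_exposure(out$rsa, scheme)
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Correlation between site entropy and RSA
#'
#' Product-moment (Pearson) or rank (Spearman) correlation between per-site
#' RSA and per-site entropy.  A defined correlation requires at least 3 sites
#' and non-constant values on both axes; constant input raises an error so
#' that undefined correlations are reported as missing, never as 0.
#'
#' @param entropy Named numeric vector of per-site entropies (names are
#'   structure positions) or unnamed vector parallel to `rsa`.
#' @param rsa Numeric vector of per-site RSA values, parallel to `entropy`.
#' @param method `"pearson"` or `"spearman"`.
#' @param protein_id,condition Optional tags copied into the result.
#' @return One-row data frame: `protein_id`, `condition`, `method`, `r`,
#'   `n_sites`.
#' @export
entropy_rsa_correlation <- function(entropy, rsa,
                                    method = c("pearson", "spearman"),
                                    protein_id = NA_character_,
                                    condition = NA_character_) {
  method <- match.arg(method)
  ok <- is.finite(entropy) & is.finite(rsa)
  x <- rsa[ok]; y <- entropy[ok]
  if (length(x) < 3L)
    stop("need at least 3 sites with finite entropy and RSA")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("correlation undefined: constant input on one axis")
  r <- stats::cor(x, y, method = method)
  data.frame(protein_id = protein_id, condition = condition, method = method,
             r = r, n_sites = length(x))
}

#' Exposure-class entropy summaries across proteins
#'
#' For each protein and condition, computes the mean site entropy within each
#' exposure class; then summarizes each (condition, class) cell across
#' proteins by its median and mean.  This is the tabular form behind
#' median-by-class comparisons of designed versus natural variability.
#'
#' @param per_site_tables Named list (one element per protein) of data frames
#'   with columns `exposure_class` and one `entropy_<condition>` column per
#'   alignment set (as produced by [compare_designs()]'s `per_site` table).
#' @return List with `per_protein` (protein, condition, class, mean_entropy)
#'   and `summary` (condition, class, median_entropy, mean_entropy,
#'   n_proteins); empty classes are reported as `NA`.
#' @export
class_entropy_summary <- function(per_site_tables) {
  stopifnot(is.list(per_site_tables), length(per_site_tables) >= 1L)
  if (is.null(names(per_site_tables)))
    names(per_site_tables) <- paste0("protein_", seq_along(per_site_tables))
  rows <- list()
  for (pid in names(per_site_tables)) {
    tab <- per_site_tables[[pid]]
    ent_cols <- grep("^entropy_", names(tab), value = TRUE)
    if (length(ent_cols) == 0L)
      stop("no 'entropy_<condition>' columns in table for ", pid)
    for (col in ent_cols) {
      cond <- sub("^entropy_", "", col)
      means <- tapply(tab[[col]], tab$exposure_class, mean)
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = pid, condition = cond,
        exposure_class = names(means),
        mean_entropy = as.numeric(means))
    }
  }
  per_protein <- do.call(rbind, rows)
  agg <- stats::aggregate(mean_entropy ~ condition + exposure_class,
                          data = per_protein,
                          FUN = function(v) c(median = stats::median(v),
                                              mean = mean(v),
                                              n = sum(is.finite(v))),
                          na.action = stats::na.pass)
  summary_df <- data.frame(condition = agg$condition,
                           exposure_class = agg$exposure_class,
                           median_entropy = agg$mean_entropy[, "median"],
                           mean_entropy = agg$mean_entropy[, "mean"],
                           n_proteins = agg$mean_entropy[, "n"])
  list(per_protein = per_protein, summary = summary_df)
}

#' Exposure-stratified amino-acid frequencies pooled over proteins
#'
#' Pools raw amino-acid counts over all sites of all proteins, separately for
#' each exposure class of a two-class scheme, and normalizes to descriptive
#' frequencies (no pseudocount).
#'
#' @param alignments List of `aa_alignment` objects (one source set, e.g. all
#'   natural alignments).
#' @param maps Parallel list of `site_map`s.
#' @param rsas Parallel list of `rsa_profile`s.
#' @param scheme A two-class [exposure_scheme()].
#' @param alphabet An [aa_alphabet()].
#' @return Numeric matrix with one row per exposure class and 20 columns;
#'   rows sum to 1 where the class is non-empty, and are `NA` (flagged via
#'   the `empty_classes` attribute) otherwise.
#' @export
class_aa_frequencies <- function(alignments, maps, rsas,
                                 scheme = exposure_scheme("two_class"),
                                 alphabet = aa_alphabet()) {
  if (scheme$scheme_name != "two_class")
    stop("class_aa_frequencies uses the two-class exposure scheme")
  if (length(alignments) != length(maps) || length(maps) != length(rsas))
    stop("'alignments', 'maps' and 'rsas' must have the same length")
  classes <- c("buried", "exposed")
  pooled <- matrix(0, nrow = 2L, ncol = 20L,
                   dimnames = list(classes, alphabet$letters))
  for (k in seq_along(alignments)) {
    counts <- suppressWarnings(column_counts(alignments[[k]], maps[[k]], alphabet))
    joined <- join_site_table(maps[[k]], rsas[[k]], scheme)
    idx <- match(joined$position, as.integer(rownames(counts)))
    keep <- !is.na(idx)
    cls <- joined$exposure_class[keep]
    cmat <- unclass(counts)[idx[keep], , drop = FALSE]
    for (cl in classes) {
      sel <- cls == cl
      if (any(sel)) pooled[cl, ] <- pooled[cl, ] + colSums(cmat[sel, , drop = FALSE])
    }
  }
  totals <- rowSums(pooled)
  freqs <- pooled / ifelse(totals > 0, totals, NA_real_)
  attr(freqs, "empty_classes") <- classes[totals == 0]
  freqs
}

#' Distribution summaries per design condition
#'
#' Summarizes per-protein metrics (mean entropy, mean KL, mean rank-KL,
#' entropy-RSA correlation) across proteins for each condition: minimum,
#' quartiles (linear-interpolation convention), median, mean and maximum.
#'
#' @param per_protein Data frame with columns `condition`, `metric`, `value`
#'   (long form), or a wide data frame with a `condition` column and numeric
#'   metric columns (it is melted automatically).
#' @return Data frame: condition, metric, n, min, q1, median, mean, q3, max.
#' @export
summarize_conditions <- function(per_protein) {
  stopifnot(is.data.frame(per_protein), "condition" %in% names(per_protein))
  if (!all(c("metric", "value") %in% names(per_protein))) {
    num_cols <- names(per_protein)[vapply(per_protein, is.numeric, logical(1))]
    long <- do.call(rbind, lapply(num_cols, function(m) {
      data.frame(condition = per_protein$condition, metric = m,
                 value = per_protein[[m]])
    }))
  } else long <- per_protein[, c("condition", "metric", "value")]
  long <- long[is.finite(long$value), , drop = FALSE]
  if (nrow(long) == 0L) stop("no finite values to summarize")
  out <- do.call(rbind, lapply(split(long, list(long$condition, long$metric),
                                     drop = TRUE), function(d) {
    qs <- stats::quantile(d$value, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(condition = d$condition[1L], metric = d$metric[1L],
               n = nrow(d), min = min(d$value), q1 = qs[1L], median = qs[2L],
               mean = mean(d$value), q3 = qs[3L], max = max(d$value))
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$condition), ]
}

#' Paired comparison of a metric between two conditions
#'
#' Convenience wrapper around a paired t-test for per-protein metrics under
#' two conditions (plumbing only; interpret with the usual caveats at small
#' protein counts).
#'
#' @param x,y Numeric vectors of per-protein values, paired by protein.
#' @return List with `estimate` (mean difference x - y), `p_value`, `n`.
#' @export
paired_condition_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 2L) stop("need at least 2 complete pairs")
  ht <- stats::t.test(x[ok], y[ok], paired = TRUE)
  list(estimate = unname(ht$estimate), p_value = ht$p.value, n = sum(ok))
}
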