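#' Compare designed alignments to a natural alignment for one protein
#'
#' The central per-protein analysis: computes per-site entropies (raw
#' frequencies) for the natural alignment and every design condition,
#' standard and rank-ordered KL divergence of each design condition against
#' the natural reference (both profiles pseudocounted), joins everything with
#' the RSA profile of the native structure, and derives per-condition
#' summaries: mean entropy, mean KL, mean rank-KL and the entropy-RSA
#' correlation.  Optionally adds the split-half natural-vs-natural control.
#'
#' @param natural `aa_alignment` of natural homologs (the reference set).
#' @param designs Named list of `aa_alignment` objects, one per design
#'   condition; names are the condition tags.
#' @param rsa `rsa_profile` of the native structure, RSA values computed.
#' @param map Optional `site_map`; defaults to the natural alignment's map.
#'   All alignments must share it (designs are coordinate-identical to the
#'   native structure).
#' @param method Correlation method (`"pearson"` or `"spearman"`).
#' @param scheme [exposure_scheme()] for the per-site exposure classes.
#' @param control_seed If non-`NULL`, compute [split_half_control()] of the
#'   natural alignment with this seed.
#' @param control_reps Number of split-half repetitions to average.
#' @param entropy_pseudocount Apply the 1/20 pseudocount to entropy
#'   calculations as well?  Off by default: the pseudocount is a device for
#'   the KL divergence, where zero reference frequencies are fatal.
#' @param protein_id Tag identifying the protein in reports.
#' @param alphabet An [aa_alphabet()].
#' @return Object of class `design_comparison`: list with `per_site` (data
#'   frame: position, rsa, exposure_class, `entropy_natural`,
#'   `entropy_<cond>`, `kl_<cond>`, `rank_kl_<cond>`), `per_condition`
#'   (data frame of per-condition summaries), `control_kl`, `protein_id`,
#'   `method`, `scheme`.
#' @examples
#' spec <- synthetic_spec(n_sites = 40, n_natural_seqs = 30,
#'                        n_design_seqs = 30, temperatures = c(0.1, 1.2))
#' rsa <- sample_rsa_profile(spec)
#' nat <- generate_natural_alignment(spec, rsa)$alignment
#' des <- lapply(c(0.1, 1.2), function(T)
#'   generate_design_alignment(spec, rsa, T)$alignment)
#' names(des) <- c("T0.1", "T1.2")
#' cmp <- compare_designs(nat, des, rsa, control_seed = 1)
#' summary(cmp)
#' @export
compare_designs <- function(natural, designs, rsa, map = NULL,
                            method = c("pearson", "spearman"),
                            scheme = exposure_scheme("three_class"),
                            control_seed = NULL, control_reps = 1L,
                            entropy_pseudocount = FALSE,
                            protein_id = "protein", alphabet = aa_alphabet()) {
  method <- match.arg(method)
  stopifnot(inherits(natural, "aa_alignment"), inherits(rsa, "rsa_profile"))
  if (!is.list(designs) || length(designs) == 0L || is.null(names(designs)) ||
      any(!nzchar(names(designs))))
    stop("'designs' must be a non-empty named list of alignments")
  if (anyDuplicated(names(designs)))
    stop("duplicate design condition tags")
  if (is.null(map)) map <- build_site_map(natural, alphabet)

  nat_counts <- suppressWarnings(column_counts(natural, map, alphabet))
  nat_H <- site_entropy(site_frequencies(nat_counts, entropy_pseudocount))
  nat_q <- site_frequencies(nat_counts, pseudocount = TRUE)

  joined <- join_site_table(map, rsa, scheme)
  joined$entropy_natural <- nat_H[match(joined$position,
                                        as.integer(names(nat_H)))]

  per_cond <- list()
  for (cond in names(designs)) {
    d <- designs[[cond]]
    stopifnot(inherits(d, "aa_alignment"))
    if (nchar(d$seqs[1L]) != nchar(natural$seqs[1L]))
      stop(sprintf("design '%s' has a different alignment width than natural",
                   cond))
    d_counts <- suppressWarnings(column_counts(d, map, alphabet))
    if (!identical(rownames(d_counts), rownames(nat_counts)))
      stop(sprintf("design '%s' covers different sites than the natural alignment",
                   cond))
    d_H <- site_entropy(site_frequencies(d_counts, entropy_pseudocount))
    d_p <- site_frequencies(d_counts, pseudocount = TRUE)
    kl <- kl_divergence(d_p, nat_q)
    rkl <- rank_ordered_kl(d_p, nat_q)
    idx <- match(joined$position, as.integer(names(d_H)))
    joined[[paste0("entropy_", cond)]] <- d_H[idx]
    joined[[paste0("kl_", cond)]] <- kl[idx]
    joined[[paste0("rank_kl_", cond)]] <- rkl[idx]
    r <- entropy_rsa_correlation(d_H[idx], joined$rsa, method = method,
                                 protein_id = protein_id, condition = cond)
    per_cond[[cond]] <- data.frame(
      protein_id = protein_id, condition = cond,
      mean_entropy = mean_entropy(d_H),
      mean_kl = mean_divergence(kl),
      mean_rank_kl = mean_divergence(rkl),
      cor_r = r$r, cor_n = r$n_sites)
  }
  nat_r <- entropy_rsa_correlation(joined$entropy_natural, joined$rsa,
                                   method = method, protein_id = protein_id,
                                   condition = "natural")
  per_condition <- rbind(
    data.frame(protein_id = protein_id, condition = "natural",
               mean_entropy = mean_entropy(nat_H),
               mean_kl = NA_real_, mean_rank_kl = NA_real_,
               cor_r = nat_r$r, cor_n = nat_r$n_sites),
    do.call(rbind, per_cond))
  rownames(per_condition) <- NULL

  control_kl <- NA_real_
  if (!is.null(control_seed))
    control_kl <- split_half_control(natural, map, seed = control_seed,
                                     reps = control_reps, alphabet = alphabet)

  structure(list(per_site = joined, per_condition = per_condition,
                 control_kl = control_kl, protein_id = protein_id,
                 method = method, scheme = scheme),
            class = "design_comparison")
}

#' @export
print.design_comparison <- function(x, ...) {
  cat(sprintf("Design-vs-natural comparison for '%s' (%d sites, %d conditions)\n",
              x$protein_id, nrow(x$per_site), nrow(x$per_condition) - 1L))
  if (is.finite(x$control_kl))
    cat(sprintf("  split-half control KL: %.4f nats\n", x$control_kl))
  cat("Use summary() for the per-condition table.\n")
  invisible(x)
}

#' @export
summary.design_comparison <- function(object, digits = 4, ...) {
  cat(sprintf("Protein '%s': per-condition summaries (%s correlation)\n",
              object$protein_id, object$method))
  tab <- object$per_condition
  tab[, sapply(tab, is.numeric)] <- round(tab[, sapply(tab, is.numeric)], digits)
  print(tab, row.names = FALSE)
  if (is.finite(object$control_kl))
    cat(sprintf("Split-half natural control KL: %.4f nats\n", object$control_kl))
  invisible(object$per_condition)
}

#' @export
plot.design_comparison <- function(x, condition = NULL, ...) {
  ps <- x$per_site
  if (is.null(condition)) {
    cols <- grep("^entropy_", names(ps), value = TRUE)
    condition <- sub("^entropy_", "", setdiff(cols, "entropy_natural")[1L])
  }
  ycol <- paste0("entropy_", condition)
  if (!ycol %in% names(ps)) stop("unknown condition: ", condition)
  graphics::plot(ps$rsa, ps$entropy_natural, pch = 16, col = "grey30",
                 xlab = "RSA", ylab = "Site entropy (nats)",
                 main = sprintf("%s: natural vs %s", x$protein_id, condition),
                 ylim = range(c(ps$entropy_natural, ps[[ycol]]), finite = TRUE),
                 ...)
  graphics::points(ps$rsa, ps[[ycol]], pch = 1, col = "firebrick")
  graphics::legend("topleft", legend = c("natural", condition),
                   pch = c(16, 1), col = c("grey30", "firebrick"), bty = "n")
  invisible(x)
}

#' Aggregate per-protein comparisons into a dataset report
#'
#' Binds the per-condition tables of several [compare_designs()] results and
#' attaches condition-level distribution summaries.
#'
#' @param comparisons List of `design_comparison` objects.
#' @return Object of class `comparison_report`: list with `per_protein`
#'   (row-bound per-condition tables plus `control_kl`), `condition_summary`
#'   (see [summarize_conditions()]) and `per_site_tables` (named list used by
#'   [class_entropy_summary()] and [select_hybrid_recipe()]).
#' @export
comparison_report <- function(comparisons) {
  stopifnot(is.list(comparisons), length(comparisons) >= 1L)
  ok <- vapply(comparisons, inherits, logical(1), "design_comparison")
  if (!all(ok)) stop("all elements must be 'design_comparison' objects")
  per_protein <- do.call(rbind, lapply(comparisons, function(cmp) {
    tab <- cmp$per_condition
    tab$control_kl <- ifelse(tab$condition == "natural", cmp$control_kl,
                             NA_real_)
    tab
  }))
  rownames(per_protein) <- NULL
  metrics <- per_protein[, c("condition", "mean_entropy", "mean_kl",
                             "mean_rank_kl", "cor_r")]
  per_site_tables <- lapply(comparisons, `[[`, "per_site")
  names(per_site_tables) <- vapply(comparisons, `[[`, character(1),
                                   "protein_id")
  structure(list(per_protein = per_protein,
                 condition_summary = summarize_conditions(metrics),
                 per_site_tables = per_site_tables),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  n_prot <- length(unique(x$per_protein$protein_id))
  cat(sprintf("Comparison report: %d protein(s), %d condition(s)\n", n_prot,
              length(unique(x$per_protein$condition))))
  cat("Use summary() for condition-level distribution summaries.\n")
  invisible(x)
}

#' @export
summary.comparison_report <- function(object, digits = 4, ...) {
  tab <- object$condition_summary
  num <- vapply(tab, is.numeric, logical(1))
  tab[, num] <- round(tab[, num], digits)
  print(tab, row.names = FALSE)
  invisible(object$condition_summary)
}

#' @export
plot.comparison_report <- function(x, metric = "mean_entropy", ...) {
  pp <- x$per_protein
  if (!metric %in% names(pp)) stop("unknown metric: ", metric)
  conds <- unique(pp$condition)
  vals <- lapply(conds, function(cn) pp[[metric]][pp$condition == cn])
  names(vals) <- conds
  vals <- vals[vapply(vals, function(v) any(is.finite(v)), logical(1))]
  graphics::boxplot(vals, las = 2, ylab = metric,
                    main = sprintf("%s by condition", metric), ...)
  invisible(x)
}
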