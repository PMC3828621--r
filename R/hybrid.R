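#' Recipe for a hybrid design alignment
#'
#' A hybrid design takes buried and partially buried columns from sequences
#' designed under one condition (the core condition, typically a lower design
#' temperature) and exposed columns from another (the surface condition,
#' typically a higher temperature).  Hybrids are diagnostic constructs — they
#' show how much more variable surfaces would need to be relative to cores —
#' not realistic designable sequences.
#'
#' @param core_condition Condition tag supplying buried + partially buried
#'   columns.
#' @param surface_condition Condition tag supplying exposed columns.
#' @param scheme A three-class [exposure_scheme()].
#' @return Object of class `hybrid_recipe`.
#' @export
hybrid_recipe <- function(core_condition, surface_condition,
                          scheme = exposure_scheme("three_class")) {
  stopifnot(inherits(scheme, "exposure_scheme"))
  if (scheme$scheme_name != "three_class")
    stop("hybrid recipes use the three-class exposure scheme")
  structure(list(core_condition = as.character(core_condition),
                 surface_condition = as.character(surface_condition),
                 scheme = scheme),
            class = "hybrid_recipe")
}

#' Build a hybrid design alignment
#'
#' Splices two design alignments column-by-column: at every structure position
#' classed buried or partially buried the hybrid takes the core alignment's
#' column, and at exposed positions the surface alignment's column.  Columns
#' not covered by the site map (reference-gap columns) are taken from the core
#' alignment.  Row k of the hybrid concatenates columns from row k of each
#' source, so the output is a well-formed alignment; column-wise statistics
#' are unaffected by this pairing choice.
#'
#' @param core `aa_alignment` designed under the core condition.
#' @param surface `aa_alignment` designed under the surface condition; must
#'   have the same dimensions and the same site map as `core`.
#' @param map Shared `site_map` of both alignments.
#' @param rsa `rsa_profile` on the native structure.
#' @param recipe A [hybrid_recipe()].
#' @return An `aa_alignment` with `source_label = "hybrid"` and a condition
#'   tag `<core>+<surface>`.
#' @export
build_hybrid <- function(core, surface, map, rsa, recipe) {
  stopifnot(inherits(core, "aa_alignment"), inherits(surface, "aa_alignment"),
            inherits(recipe, "hybrid_recipe"))
  if (nchar(core$seqs[1L]) != nchar(surface$seqs[1L]))
    stop("core and surface alignments have different widths")
  if (length(core$ids) != length(surface$ids))
    stop("core and surface alignments have different record counts")
  missing_pos <- setdiff(map$position, rsa$position)
  if (length(missing_pos) > 0L)
    stop("mapped position(s) absent from RSA profile: ",
         paste(missing_pos, collapse = ", "))
  if (anyNA(rsa$rsa)) stop("RSA values not computed; run compute_rsa() first")

  cls <- classify_exposure(rsa$rsa[match(map$position, rsa$position)],
                           recipe$scheme)
  exposed_cols <- map$column[cls == "exposed"]

  cmat <- do.call(rbind, strsplit(core$seqs, "", fixed = TRUE))
  smat <- do.call(rbind, strsplit(surface$seqs, "", fixed = TRUE))
  hmat <- cmat
  hmat[, exposed_cols] <- smat[, exposed_cols]
  alignment(ids = core$ids,
            seqs = apply(hmat, 1L, paste0, collapse = ""),
            reference_id = core$reference_id,
            source_label = "hybrid",
            condition = paste0(recipe$core_condition, "+",
                               recipe$surface_condition))
}

#' Entropy-RSA correlations of a hybrid and its natural counterpart
#'
#' Computes per-site entropies (raw frequencies) for the hybrid and the
#' natural alignment at the mapped positions shared with the RSA profile, and
#' returns the entropy-RSA correlation of each, paired for one protein.
#'
#' @param hybrid,natural `aa_alignment` objects sharing `map`.
#' @param map Shared `site_map`.
#' @param rsa `rsa_profile` on the native structure.
#' @param method Correlation method, see [entropy_rsa_correlation()].
#' @param protein_id Optional tag copied into the result.
#' @param alphabet An [aa_alphabet()].
#' @return Two-row data frame (conditions `hybrid` and `natural`) in the
#'   format of [entropy_rsa_correlation()].
#' @export
hybrid_correlation_analysis <- function(hybrid, natural, map, rsa,
                                        method = "pearson",
                                        protein_id = NA_character_,
                                        alphabet = aa_alphabet()) {
  joined <- join_site_table(map, rsa, exposure_scheme("three_class"))
  one <- function(aln, cond) {
    counts <- suppressWarnings(column_counts(aln, map, alphabet))
    H <- site_entropy(site_frequencies(counts))
    idx <- match(joined$position, as.integer(names(H)))
    entropy_rsa_correlation(H[idx], joined$rsa, method = method,
                            protein_id = protein_id, condition = cond)
  }
  rbind(one(hybrid, hybrid$condition), one(natural, "natural"))
}

#' Choose a hybrid recipe by pooled class-entropy matching
#'
#' Implements the dataset-level selection of core and surface conditions: the
#' core condition is the one whose across-protein median mean entropy at
#' buried plus partially buried sites is closest to the natural value, and the
#' surface condition the one closest at exposed sites.
#'
#' @param per_site_tables As in [class_entropy_summary()]: named list of
#'   per-protein site tables with `exposure_class` and `entropy_<condition>`
#'   columns (including `entropy_natural`).
#' @return A [hybrid_recipe()] with the selected conditions.
#' @export
select_hybrid_recipe <- function(per_site_tables) {
  med_class <- function(col, classes) {
    stats::median(vapply(per_site_tables, function(tab) {
      sel <- tab$exposure_class %in% classes
      mean(tab[[col]][sel])
    }, numeric(1)), na.rm = TRUE)
  }
  ent_cols <- grep("^entropy_", names(per_site_tables[[1L]]), value = TRUE)
  design_cols <- setdiff(ent_cols, "entropy_natural")
  if (length(design_cols) < 2L)
    stop("need at least two design conditions to select a hybrid recipe")
  conds <- sub("^entropy_", "", design_cols)
  nat_core <- med_class("entropy_natural", c("buried", "partially_buried"))
  nat_surf <- med_class("entropy_natural", "exposed")
  des_core <- vapply(design_cols, med_class,
                     classes = c("buried", "partially_buried"), numeric(1))
  des_surf <- vapply(design_cols, med_class, classes = "exposed", numeric(1))
  hybrid_recipe(core_condition = conds[which.min(abs(des_core - nat_core))],
                surface_condition = conds[which.min(abs(des_surf - nat_surf))])
}
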