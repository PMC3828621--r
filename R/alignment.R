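#' Construct a protein multiple sequence alignment object
#'
#' An `aa_alignment` holds equal-length aligned amino-acid sequences plus the
#' identity of a reference row whose ungapped sequence corresponds to the
#' residues of the native structure.  All downstream per-site statistics are
#' computed at the reference's non-gap columns only, so the reference row is
#' what ties alignment columns to structure positions (and hence to RSA
#' values).
#'
#' Sequences are uppercased on construction.  Characters outside the canonical
#' 20 letters, the gap symbols and the unknown symbols are replaced by `"X"`
#' with a warning giving the replacement count.
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of aligned sequences, same length as `ids`,
#'   all of identical width.
#' @param reference_id Id of the reference row, or `"first"` to take the
#'   first record.
#' @param source_label Free tag describing the origin of the set, e.g.
#'   `"natural"`, `"designed"`, `"hybrid"`.
#' @param condition Optional design-condition tag (e.g. `"FB"`, `"T0.6"`).
#' @param alphabet An [aa_alphabet()].
#'
#' @return Object of class `aa_alignment`: list with elements `ids`, `seqs`,
#'   `reference_id`, `source_label`, `condition`.
#' @examples
#' aln <- alignment(c("ref", "s1"), c("ACDE", "ACDF"))
#' aln$reference_id
#' @export
alignment <- function(ids, seqs, reference_id = "first",
                      source_label = "unlabelled", condition = NA_character_,
                      alphabet = aa_alphabet()) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs))
    stop("'ids' and 'seqs' must have the same length")
  if (length(ids) < 2L)
    stop("an alignment needs at least 2 records")
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    bad <- ids[widths != widths[1L]][1L]
    stop(sprintf("ragged alignment: record '%s' has length %d, expected %d",
                 bad, nchar(seqs[ids == bad]), widths[1L]))
  }
  if (widths[1L] == 0L) stop("alignment has zero columns")
  if (identical(reference_id, "first")) reference_id <- ids[1L]
  if (!reference_id %in% ids)
    stop(sprintf("reference_id '%s' not found among records", reference_id))

  allowed <- c(alphabet$letters, alphabet$gap_symbols, alphabet$unknown_symbols)
  chars <- strsplit(seqs, "", fixed = TRUE)
  n_bad <- sum(vapply(chars, function(x) sum(!x %in% allowed), integer(1)))
  if (n_bad > 0L) {
    warning(sprintf("%d unrecognized character(s) mapped to unknown ('X')", n_bad))
    seqs <- vapply(chars, function(x) {
      x[!x %in% allowed] <- "X"
      paste0(x, collapse = "")
    }, character(1))
  }

  structure(
    list(ids = ids, seqs = seqs, reference_id = reference_id,
         source_label = source_label, condition = condition),
    class = "aa_alignment"
  )
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d records x %d columns\n",
              length(x$ids), nchar(x$seqs[1L])))
  cat(sprintf("  reference: %s | source: %s | condition: %s\n",
              x$reference_id, x$source_label,
              ifelse(is.na(x$condition), "-", x$condition)))
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Reads an aligned FASTA file into an [alignment()] object.  All records must
#' have the same aligned length.  Parsing is case-insensitive; unrecognized
#' characters are mapped to unknown with a warning.
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_id Id of the reference record, or `"first"` (default).
#' @param source_label,condition Tags stored on the alignment, see
#'   [alignment()].
#' @param alphabet An [aa_alphabet()].
#' @return An `aa_alignment`.
#' @seealso [write_alignment()]
#' @export
read_alignment <- function(path, reference_id = "first",
                           source_label = "unlabelled",
                           condition = NA_character_,
                           alphabet = aa_alphabet()) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  alignment(ids = ids, seqs = as.character(set), reference_id = reference_id,
            source_label = source_label, condition = condition,
            alphabet = alphabet)
}

#' Write an alignment to FASTA
#'
#' The reference record keeps its id; re-reading the file with
#' `read_alignment(path, reference_id = aln$reference_id)` round-trips the
#' alignment exactly.
#'
#' @param aln An `aa_alignment`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aa_alignment"))
  set <- Biostrings::BStringSet(aln$seqs)
  names(set) <- aln$ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Map alignment columns to structure positions
#'
#' Builds the bridge between alignment columns and native-structure residue
#' numbering: one entry per non-gap character of the reference row.  Columns
#' where the reference is gapped (e.g. insertion columns of a Pfam alignment
#' relative to the structure) are excluded from all downstream statistics.
#'
#' @param aln An `aa_alignment`.
#' @param alphabet An [aa_alphabet()].
#' @return A `site_map`: data frame with integer columns `column` (1-based
#'   alignment column) and `position` (1-based structure position along the
#'   reference's ungapped sequence), both strictly increasing.
#' @examples
#' aln <- alignment(c("r", "s"), c("A-CD", "AACD"))
#' build_site_map(aln)
#' @export
build_site_map <- function(aln, alphabet = aa_alphabet()) {
  stopifnot(inherits(aln, "aa_alignment"))
  ref <- aln$seqs[match(aln$reference_id, aln$ids)]
  chars <- strsplit(ref, "", fixed = TRUE)[[1L]]
  keep <- !(chars %in% alphabet$gap_symbols)
  if (!any(keep))
    stop("reference sequence consists only of gaps")
  map <- data.frame(column = which(keep),
                    position = seq_len(sum(keep)))
  class(map) <- c("site_map", "data.frame")
  map
}

#' Per-site amino-acid counts
#'
#' Counts the 20 canonical amino acids in each mapped alignment column.  Gap
#' and unknown characters are excluded from both the counts and the per-site
#' totals, so frequencies computed later are renormalized over observed
#' canonical residues.  Mapped sites where no countable residue remains are
#' excluded with a warning and recorded in the `excluded_positions` attribute.
#'
#' @param aln An `aa_alignment`.
#' @param map A `site_map` from [build_site_map()]; defaults to the map of
#'   `aln` itself.
#' @param alphabet An [aa_alphabet()].
#' @return A `count_matrix`: integer matrix with one row per retained
#'   structure position (row names are positions) and 20 columns (the
#'   canonical letters), with attributes `site_totals` (integer vector) and
#'   `excluded_positions` (integer vector, possibly empty).
#' @examples
#' aln <- alignment(c("r", "s", "t"), c("IA", "IA", "LA"))
#' column_counts(aln)
#' @export
column_counts <- function(aln, map = build_site_map(aln, alphabet),
                          alphabet = aa_alphabet()) {
  stopifnot(inherits(aln, "aa_alignment"))
  mat <- do.call(rbind, strsplit(aln$seqs, "", fixed = TRUE))
  counts <- matrix(0L, nrow = nrow(map), ncol = 20L,
                   dimnames = list(map$position, alphabet$letters))
  for (i in seq_len(nrow(map))) {
    col <- mat[, map$column[i]]
    tab <- tabulate(factor(col, levels = alphabet$letters), nbins = 20L)
    counts[i, ] <- tab
  }
  totals <- as.integer(rowSums(counts))
  empty <- totals == 0L
  excluded <- as.integer(map$position[empty])
  if (any(empty)) {
    warning(sprintf("%d mapped site(s) with no countable residues excluded: %s",
                    sum(empty), paste(excluded, collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
    totals <- totals[!empty]
  }
  structure(counts,
            site_totals = totals,
            excluded_positions = excluded,
            class = c("count_matrix", class(counts)))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Per-site count matrix: %d sites x 20 letters (max site total %d)\n",
              nrow(x), max(attr(x, "site_totals"))))
  invisible(x)
}
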