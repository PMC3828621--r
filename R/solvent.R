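#' Parse classic DSSP output for one chain
#'
#' Reads a classic (fixed-column, text) DSSP output file and extracts, for
#' every residue of the requested chain, the one-letter amino-acid code and
#' the absolute solvent accessibility (the `ACC` field, in square Angstrom).
#' Residues are renumbered 1..n in order of appearance within the chain, which
#' matches the structure-position numbering used by [build_site_map()] when
#' the reference sequence is the chain's sequence.  Chain-break records
#' (`!` / `!*`) are skipped with a logged count.  Lowercase letters in the AA
#' column (DSSP's notation for disulfide-bonded cysteines) are read as `C`.
#' mmCIF-style DSSP output is rejected.
#'
#' @param path Path to a classic DSSP output file.
#' @param chain Single chain identifier (one character).
#' @return An `rsa_profile` data frame with columns `position`, `aa`, `asa`
#'   and `rsa` (the latter `NA` until [compute_rsa()] is applied).
#' @seealso [compute_rsa()], [read_rsa_table()]
#' @export
parse_dssp <- function(path, chain) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (!is.character(chain) || nchar(chain) != 1L)
    stop("'chain' must be a single character")
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty DSSP file: ", path)
  if (grepl("^data_", lines[1L]))
    stop("mmCIF-style DSSP output is not supported; provide classic text output")
  hdr <- grep("^  #  RESIDUE", lines)
  if (length(hdr) == 0L)
    stop("missing DSSP residue-table header ('  #  RESIDUE ...'); not classic DSSP output")
  body <- lines[(hdr[1L] + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]

  aa_col <- substr(body, 14L, 14L)
  chain_col <- substr(body, 12L, 12L)
  breaks <- aa_col == "!"
  if (any(breaks))
    message(sprintf("parse_dssp: skipped %d chain-break/missing-density record(s)",
                    sum(breaks)))
  body <- body[!breaks]
  aa_col <- aa_col[!breaks]
  chain_col <- chain_col[!breaks]

  available <- sort(unique(chain_col))
  sel <- chain_col == chain
  if (!any(sel))
    stop(sprintf("chain '%s' not present; available chains: %s",
                 chain, paste(available, collapse = ", ")))
  body <- body[sel]
  aa <- toupper(aa_col[sel])  # lowercase = SS-bonded Cys
  aa[aa_col[sel] %in% letters] <- "C"
  acc_txt <- trimws(substr(body, 35L, 38L))
  acc <- suppressWarnings(as.numeric(acc_txt))
  if (anyNA(acc)) {
    bad <- which(is.na(acc))[1L]
    stop(sprintf("non-numeric ACC field '%s' in DSSP residue line %d",
                 acc_txt[bad], bad))
  }
  out <- data.frame(position = seq_along(acc), aa = aa, asa = acc,
                    rsa = NA_real_)
  class(out) <- c("rsa_profile", "data.frame")
  out
}

#' Convert absolute to relative solvent accessibility
#'
#' Computes per-residue RSA by dividing each residue's absolute accessibility
#' (ASA) by the maximum possible ASA of that residue type.  RSA values above 1
#' can occur with theoretical max-ASA scales and are retained (clipping would
#' bias the exposed class); their count is reported as a message.
#'
#' @param profile An `rsa_profile` with an `asa` column (e.g. from
#'   [parse_dssp()]).
#' @param max_asa Named numeric vector of per-letter maximum ASA values, see
#'   [max_asa_table()].
#' @return The profile with its `rsa` column filled.
#' @export
compute_rsa <- function(profile, max_asa = max_asa_table()) {
  stopifnot(inherits(profile, "rsa_profile"))
  missing_aa <- setdiff(unique(profile$aa), names(max_asa))
  if (length(missing_aa) > 0L)
    stop("residue letter(s) missing from max-ASA table: ",
         paste(missing_aa, collapse = ", "))
  if (any(profile$asa < 0, na.rm = TRUE)) stop("negative ASA value")
  profile$rsa <- profile$asa / unname(max_asa[profile$aa])
  n_over <- sum(profile$rsa > 1)
  if (n_over > 0L)
    message(sprintf("compute_rsa: %d residue(s) with RSA > 1 (retained)", n_over))
  profile
}

#' Exposure classification scheme
#'
#' RSA thresholds defining residue exposure classes.  The three-class scheme
#' is buried (RSA <= `buried_max`), partially buried
#' (`buried_max` < RSA <= `partial_max`) and exposed (RSA > `partial_max`);
#' the two-class scheme splits at `buried_max` only.  Defaults are 0.05
#' and 0.25.
#'
#' @param scheme_name `"three_class"` or `"two_class"`.
#' @param buried_max Upper RSA bound (inclusive) of the buried class.
#' @param partial_max Upper RSA bound (inclusive) of the partially buried
#'   class (three-class only).
#' @return Object of class `exposure_scheme`.
#' @export
exposure_scheme <- function(scheme_name = c("three_class", "two_class"),
                            buried_max = 0.05, partial_max = 0.25) {
  scheme_name <- match.arg(scheme_name)
  stopifnot_scalar_number(buried_max, "buried_max", positive = TRUE)
  if (buried_max >= 1) stop("'buried_max' must be < 1")
  if (scheme_name == "three_class") {
    stopifnot_scalar_number(partial_max, "partial_max", positive = TRUE)
    if (!(buried_max < partial_max && partial_max < 1))
      stop("need 0 < buried_max < partial_max < 1")
  }
  structure(list(scheme_name = scheme_name, buried_max = buried_max,
                 partial_max = partial_max),
            class = "exposure_scheme")
}

#' Classify residues by solvent exposure
#'
#' @param rsa Numeric vector of RSA values (>= 0).
#' @param scheme An [exposure_scheme()].
#' @return Factor with levels `buried`, `partially_buried`, `exposed`
#'   (three-class) or `buried`, `exposed` (two-class).
#' @examples
#' classify_exposure(c(0.05, 0.25, 0.26))
#' @export
classify_exposure <- function(rsa, scheme = exposure_scheme()) {
  stopifnot(inherits(scheme, "exposure_scheme"))
  if (any(!is.finite(rsa)) || any(rsa < 0))
    stop("RSA values must be finite and >= 0")
  if (scheme$scheme_name == "three_class") {
    cls <- ifelse(rsa <= scheme$buried_max, "buried",
                  ifelse(rsa <= scheme$partial_max, "partially_buried",
                         "exposed"))
    factor(cls, levels = c("buried", "partially_buried", "exposed"))
  } else {
    factor(ifelse(rsa <= scheme$buried_max, "buried", "exposed"),
           levels = c("buried", "exposed"))
  }
}

#' Read a precomputed RSA table
#'
#' Reads a tab-separated table with columns `position`, `aa`, optionally
#' `asa`, and `rsa` — the dialect written by [write_rsa_table()] — allowing
#' users to bypass DSSP entirely.
#'
#' @param path Path to a TSV file.
#' @return An `rsa_profile` data frame.
#' @export
read_rsa_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("position", "aa", "rsa")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0L)
    stop("RSA table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"asa" %in% names(tab)) tab$asa <- NA_real_
  if (anyDuplicated(tab$position))
    stop("duplicate structure position(s) in RSA table: ",
         paste(unique(tab$position[duplicated(tab$position)]), collapse = ", "))
  if (any(!is.finite(tab$rsa)) || any(tab$rsa < 0))
    stop("RSA values must be finite and >= 0")
  tab <- tab[order(tab$position), c("position", "aa", "asa", "rsa")]
  rownames(tab) <- NULL
  class(tab) <- c("rsa_profile", "data.frame")
  tab
}

#' Write an RSA profile as a TSV table
#'
#' @param profile An `rsa_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rsa_table <- function(profile, path) {
  stopifnot(inherits(profile, "rsa_profile"))
  utils::write.table(as.data.frame(profile)[, c("position", "aa", "asa", "rsa")],
                     file = path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
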