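#' The canonical amino-acid alphabet
#'
#' Returns the fixed, ordered set of the 20 canonical one-letter amino-acid
#' codes together with the characters treated as gaps and as unknown residues.
#' The ordering is alphabetical by one-letter code and is held fixed across a
#' whole analysis so that count matrices and frequency profiles from different
#' alignments are always column-compatible.
#'
#' @param gap_symbols Characters treated as alignment gaps.
#' @param unknown_symbols Characters treated as unknown/ambiguous residues.
#'   Non-canonical letters encountered during parsing are mapped into this
#'   class.
#'
#' @return An object of class `aa_alphabet`: a list with elements `letters`
#'   (character vector of length 20), `gap_symbols` and `unknown_symbols`.
#' @examples
#' aa_alphabet()$letters
#' @export
aa_alphabet <- function(gap_symbols = c("-", "."),
                        unknown_symbols = c("X", "B", "Z", "J", "U", "O", "*")) {
  letters20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  if (any(letters20 %in% gap_symbols) || any(letters20 %in% unknown_symbols))
    stop("gap/unknown symbols must not overlap the 20 canonical letters")
  structure(
    list(letters = letters20,
         gap_symbols = gap_symbols,
         unknown_symbols = unknown_symbols),
    class = "aa_alphabet"
  )
}

#' Maximum accessible surface area per residue
#'
#' Per-residue maximum possible accessible surface area (ASA, in square
#' Angstrom), used to normalize absolute DSSP accessibilities into relative
#' solvent accessibility (RSA).  The default `"theoretical"` scale is the
#' theoretical maximum from Tien et al. (2013); the `"empirical"` scale is the
#' empirical maximum from the same study.  Users may also supply their own
#' named vector anywhere a table is accepted.
#'
#' @param scale `"theoretical"` or `"empirical"`.
#' @return Named numeric vector of length 20 (names are one-letter codes).
#' @references Tien MZ, Meyer AG, Sydykova DK, Spielman SJ, Wilke CO (2013)
#'   Maximum allowed solvent accessibilities of residues in proteins.
#'   PLoS ONE 8(11): e80635.
#' @examples
#' max_asa_table()[["G"]]
#' @export
max_asa_table <- function(scale = c("theoretical", "empirical")) {
  scale <- match.arg(scale)
  theoretical <- c(
    A = 129.0, R = 274.0, N = 195.0, D = 193.0, C = 167.0,
    Q = 225.0, E = 223.0, G = 104.0, H = 224.0, I = 197.0,
    L = 201.0, K = 236.0, M = 224.0, F = 240.0, P = 159.0,
    S = 155.0, T = 172.0, W = 285.0, Y = 263.0, V = 174.0
  )
  empirical <- c(
    A = 121.0, R = 265.0, N = 187.0, D = 187.0, C = 148.0,
    Q = 214.0, E = 214.0, G = 97.0,  H = 216.0, I = 195.0,
    L = 191.0, K = 230.0, M = 203.0, F = 228.0, P = 154.0,
    S = 143.0, T = 163.0, W = 264.0, Y = 255.0, V = 165.0
  )
  tab <- if (scale == "theoretical") theoretical else empirical
  tab[aa_alphabet()$letters]
}

# Letters counted as hydrophobic in descriptive summaries.
hydrophobic_letters <- function() c("A", "C", "F", "I", "L", "M", "V", "W", "Y")
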