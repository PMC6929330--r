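#' Canonical amino-acid alphabet (PSI-BLAST column order)
#'
#' The 20 canonical amino acids in the column order used in the header of
#' PSI-BLAST ASCII PSSM files. Every PSSM score matrix in this package has
#' exactly these 20 columns, in this order; the 400-dimensional summed
#' feature vector is indexed residue-major over the same ordering.
#'
#' @format Character vector of length 20.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Symbol used internally for non-canonical residues (X, B, Z, U, ...).
# Rows keep their scores, but the residue is excluded from composition
# counts and contributes to no row of the summed 400-dim representation.
UNKNOWN_AA <- "X"

#' Normalise a residue string to the canonical alphabet
#'
#' Upper-cases the input and maps every letter outside the 20 canonical
#' amino acids (e.g. X, B, Z, U, O, J) to the single unknown symbol `"X"`.
#'
#' @param residues character scalar or vector of single letters.
#' @return Character vector of single letters over `AA_ALPHABET` plus `"X"`.
#' @keywords internal
normalize_residues <- function(residues) {
  if (length(residues) == 1L && nchar(residues[1L]) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  residues <- toupper(residues)
  residues[!(residues %in% AA_ALPHABET)] <- UNKNOWN_AA
  residues
}
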