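#' 400-dimensional summed-PSSM feature vector
#'
#' The classical order-destroying representation: for each residue type
#' `a` and each PSSM column `j`, entry `(a, j)` is the sum of `scores[i, j]`
#' over all positions `i` whose query residue is `a`. Collapsing an N x 20
#' profile to a fixed 20 x 20 matrix makes every sequence the same size for
#' conventional classifiers, but discards the positional ordering of the
#' profile entirely: the result is invariant under any permutation of the
#' profile rows.
#'
#' Rows for residue types absent from the sequence are all zero; unknown
#' residues (`"X"`) contribute to no row. The matrix is flattened
#' residue-major: 20 consecutive blocks of 20 PSSM columns, both in
#' [AA_ALPHABET] order.
#'
#' @param profile a [pssm_profile].
#' @return Named numeric vector of length 400 with names `"<a>.<j>"`.
#' @export
summed_pssm_features <- function(profile) {
  stopifnot(inherits(profile, "pssm_profile"))
  m <- matrix(0, nrow = 20L, ncol = 20L,
              dimnames = list(AA_ALPHABET, AA_ALPHABET))
  keep <- profile$residues %in% AA_ALPHABET
  if (any(keep)) {
    sums <- rowsum(profile$scores[keep, , drop = FALSE],
                   group = profile$residues[keep])
    m[rownames(sums), ] <- sums
  }
  v <- as.vector(t(m))  # residue-major: block a holds columns j = 1..20
  names(v) <- paste(rep(AA_ALPHABET, each = 20L), AA_ALPHABET, sep = ".")
  v
}

#' Summed-feature matrix for a whole dataset
#'
#' @param dataset a `labeled_dataset`.
#' @return Numeric matrix, one row per profile, 400 columns, with a
#'   `labels` attribute carrying the dataset labels.
#' @export
summed_feature_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  x <- t(vapply(dataset$profiles, summed_pssm_features, numeric(400L)))
  attr(x, "labels") <- dataset$labels
  x
}

#' Per-class amino-acid composition
#'
#' Frequency (in percent) of each canonical amino acid over all positions
#' of all sequences of each class, the usual first look at a
#' positive-vs-negative protein set. Unknown residues are excluded from
#' both numerator and denominator, so each class's 20 frequencies sum to
#' 100.
#'
#' @param dataset a `labeled_dataset` with at least one sequence per class.
#' @return A 2 x 20 matrix (rows `negative`, `positive`; columns
#'   [AA_ALPHABET]) of percentages.
#' @export
aa_composition <- function(dataset) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  out <- matrix(NA_real_, nrow = 2L, ncol = 20L,
                dimnames = list(c("negative", "positive"), AA_ALPHABET))
  for (cl in rownames(out)) {
    res <- unlist(lapply(dataset$profiles[dataset$labels == cl],
                         `[[`, "residues"), use.names = FALSE)
    res <- res[res %in% AA_ALPHABET]
    if (length(res) == 0L)
      stop("class '", cl, "' has no sequences (or no canonical residues)")
    out[cl, ] <- 100 * tabulate(match(res, AA_ALPHABET), 20L) / length(res)
  }
  out
}
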