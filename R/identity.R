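# Pairwise sequence identity.
#
# Identity is defined as matches / alignment length of a global (Needleman-
# Wunsch) alignment with match +1, mismatch 0 and affine gaps (open 10,
# extend 0.5; the gap penalties only shape the alignment, they do not enter
# the identity value). The denominator is the full number of alignment
# columns including gap columns, which makes identity symmetric and equal to
# 1 only for identical sequences. This differs from CD-HIT's
# shorter-sequence denominator; on gap-free alignments of equal-length
# sequences the two coincide.

GAP_OPEN <- 10
GAP_EXT <- 0.5

#' Global-alignment identity between one query and many subjects
#'
#' Computed by the package's compiled Gotoh aligner (the same scoring as
#' `Biostrings::pairwiseAlignment(type = "global", gapOpening = 10,
#' gapExtension = 0.5)` with a 0/1 substitution matrix, which serves as the
#' independent cross-check in the test suite).
#'
#' @param query Single amino-acid string.
#' @param subjects Character vector of amino-acid strings.
#' @return Numeric vector of identities in `[0, 1]`, one per subject.
#' @export
identity_to_set <- function(query, subjects) {
  if (length(subjects) == 0) return(numeric(0))
  .identity_many_cpp(query, subjects, GAP_OPEN, GAP_EXT)
}

#' Pairwise global-alignment identity
#'
#' @param a,b Non-empty amino-acid strings.
#' @return Fraction of matching columns over the global alignment length.
#' @examples
#' pairwise_identity("MKVL", "MKIL")  # 0.75
#' pairwise_identity("AAAA", "CCCC") # 0
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  identity_to_set(b, a)
}

# Cheap exact upper bound on identity: matches cannot exceed the shared
# residue multiset, and the alignment has at least max(len) columns. Used to
# skip alignments that cannot reach a threshold (the analogue of CD-HIT's
# short-word filter).
identity_upper_bound <- function(counts_a, len_a, counts_b, len_b) {
  colSums(pmin(counts_a, counts_b)) / pmax(len_a, len_b)
}

letter_count_matrix <- function(sequences) {
  t(vapply(sequences, function(s) {
    tabulate(match(strsplit(s, "")[[1]], AA_LETTERS), nbins = 20)
  }, numeric(20), USE.NAMES = FALSE))
}

#' All-pairs identity matrix
#'
#' Exhaustive global-alignment identity for every sequence pair, with the
#' letter-multiset upper bound used to skip pairs that cannot reach
#' `at_least` (those entries are reported as the bound, which is `>=` the
#' true identity). With `at_least = 0` every pair is aligned exactly.
#'
#' @param sequences Character vector of amino-acid strings.
#' @param at_least Only identities that could reach this value are computed
#'   exactly; default 0 (all exact).
#' @return Symmetric numeric matrix with unit diagonal.
#' @export
identity_matrix <- function(sequences, at_least = 0) {
  n <- length(sequences)
  m <- diag(1, n)
  if (n < 2) return(m)
  cnt <- letter_count_matrix(sequences)
  lens <- nchar(sequences)
  for (i in seq_len(n - 1)) {
    js <- (i + 1):n
    bound <- colSums(pmin(t(cnt[js, , drop = FALSE]), cnt[i, ])) /
      pmax(lens[js], lens[i])
    need <- js[bound >= at_least]
    vals <- stats::setNames(bound, js)
    if (length(need) > 0) {
      vals[as.character(need)] <- identity_to_set(sequences[i], sequences[need])
    }
    m[i, js] <- m[js, i] <- vals
  }
  m
}
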