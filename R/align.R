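#' Pairwise identity and query coverage by ends-free alignment
#'
#' Aligns a query nucleotide sequence against a reference with an ends-free
#' (semi-global) dynamic-programming alignment: unaligned terminal stretches
#' of either sequence are not penalised, interior gaps are. This is the
#' comparison used throughout the package for 16S rRNA genes, where a
#' full-length gene may be compared against a reference record that covers
#' only part of it.
#'
#' Identity is the percentage of matching columns among the aligned core
#' columns (matches, mismatches and interior gap columns; the free terminal
#' overhangs are excluded). Query coverage is the percentage of query bases
#' lying inside the aligned core. Among equal-score alignments the one with
#' the most matches (then widest query core, then fewest columns) defines
#' both numbers, so the result is deterministic.
#'
#' @param query,ref non-empty nucleotide strings (case sensitive; use
#'   upper-case A/C/G/T).
#' @param match,mismatch,gap integer alignment scores; gaps are linear.
#'   Defaults reward matches (+1) and penalise mismatches (-1) and interior
#'   gaps (-2).
#' @return A list with elements `identity` and `query_coverage` (both in
#'   percent), plus `score`, `matches` and `columns` of the optimal
#'   alignment.
#' @examples
#' pairwise_identity("ACGTACGT", "ACGTACGT")$identity
#' @export
pairwise_identity <- function(query, ref, match = 1L, mismatch = -1L,
                              gap = -2L) {
  stopifnot(is.character(query), length(query) == 1L,
            is.character(ref), length(ref) == 1L)
  if (nchar(query) == 0L || nchar(ref) == 0L)
    stop("pairwise_identity: sequences must be non-empty")
  semi_global_align_cpp(query, ref, as.integer(match), as.integer(mismatch),
                        as.integer(gap))
}
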