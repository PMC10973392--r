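# Circular contig detection. A closed replicon assembled from long reads
# is emitted as a linear string whose start is repeated at its end; the
# detector scans candidate terminal-overlap lengths from longest to
# shortest and accepts the first whose Hamming mismatch fraction is within
# tolerance (substitution-tolerant, no indels).

#' Detect a terminal overlap indicating contig circularity
#'
#' Scans overlap lengths from `min(max_overlap, floor(len/2))` down to
#' `min_overlap`; a candidate length L succeeds when the prefix and suffix
#' of length L differ at no more than `floor(max_mismatch_frac * L)`
#' positions. The longest passing overlap wins and the scan is
#' deterministic.
#'
#' @param seq nucleotide string; must be longer than `2 * min_overlap`.
#' @param min_overlap smallest overlap length considered (bases).
#' @param max_overlap largest overlap length considered (bases).
#' @param max_mismatch_frac tolerated mismatch fraction within the overlap.
#' @return A list: `is_circular`, `overlap_len` (0 when linear),
#'   `mismatch_frac` (NA when linear), `trimmed_length` (NA when linear).
#' @examples
#' s <- paste(sample(c("A","C","G","T"), 5000, replace = TRUE), collapse = "")
#' r <- detect_terminal_overlap(paste0(s, substr(s, 1, 1500)),
#'                              min_overlap = 1000)
#' r$overlap_len
#' @export
detect_terminal_overlap <- function(seq, min_overlap = 1000,
                                    max_overlap = 50000,
                                    max_mismatch_frac = 0.02) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("detect_terminal_overlap: seq must be a single string")
  len <- nchar(seq)
  if (len <= 2 * min_overlap)
    stop("detect_terminal_overlap: sequence too short (length ", len,
         " <= 2 * min_overlap)")
  hit <- terminal_overlap_cpp(seq, as.integer(min_overlap),
                              as.integer(max_overlap), max_mismatch_frac)
  if (hit$overlap_len > 0) {
    list(is_circular = TRUE,
         overlap_len = as.integer(hit$overlap_len),
         mismatch_frac = hit$mismatches / hit$overlap_len,
         trimmed_length = as.integer(len - hit$overlap_len))
  } else {
    list(is_circular = FALSE, overlap_len = 0L,
         mismatch_frac = NA_real_, trimmed_length = NA_integer_)
  }
}

#' Trim the duplicated terminus of a circular contig
#'
#' @param seq the contig sequence.
#' @param result the [detect_terminal_overlap()] result for `seq`; must be
#'   circular.
#' @return `seq` with the trailing overlap removed (the rotation start is
#'   unchanged).
#' @export
circularize <- function(seq, result) {
  if (!isTRUE(result$is_circular) || result$overlap_len < 1)
    stop("circularize: called on a linear overlap result")
  substr(seq, 1L, nchar(seq) - result$overlap_len)
}

#' Detect circular contigs across a contig set
#'
#' Applies [detect_terminal_overlap()] to every contig; contigs too short
#' for the scan are reported linear.
#'
#' @param contigs named character vector of sequences.
#' @inheritParams detect_terminal_overlap
#' @return A data.frame: `contig_id`, `is_circular`, `overlap_len`,
#'   `mismatch_frac`, `trimmed_length`.
#' @export
detect_circular_contigs <- function(contigs, min_overlap = 1000,
                                    max_overlap = 50000,
                                    max_mismatch_frac = 0.02) {
  rows <- lapply(seq_along(contigs), function(i) {
    len <- nchar(contigs[[i]])
    res <- if (len > 2 * min_overlap) {
      detect_terminal_overlap(contigs[[i]], min_overlap, max_overlap,
                              max_mismatch_frac)
    } else {
      list(is_circular = FALSE, overlap_len = 0L, mismatch_frac = NA_real_,
           trimmed_length = NA_integer_)
    }
    data.frame(contig_id = names(contigs)[i],
               is_circular = res$is_circular,
               overlap_len = res$overlap_len,
               mismatch_frac = res$mismatch_frac,
               trimmed_length = res$trimmed_length)
  })
  do.call(rbind, rows)
}
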