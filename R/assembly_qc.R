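# Assembly-level quality control: summary statistics of a contig set,
# the depth-based high-quality filter, and removal of artificial
# low-complexity contigs (long mononucleotide stretches).

as_length_vector <- function(contigs) {
  if (is.character(contigs)) nchar(contigs)
  else if (is.data.frame(contigs)) contigs$length
  else if (methods::is(contigs, "DNAStringSet")) Biostrings::width(contigs)
  else stop("contigs must be a character vector, data.frame or DNAStringSet")
}

#' Assembly summary statistics
#'
#' Computes the standard contig-set summary: contig count, total bases,
#' bases in contigs >= 50 kbp, largest contig, N50 (largest-first
#' cumulative definition: the length L such that contigs >= L hold at
#' least half the total bases), number of contigs >= 1 Mbp, and circular
#' contig count when circularity flags are supplied.
#'
#' @param contigs named character vector of sequences, data.frame with a
#'   `length` column, or `DNAStringSet`.
#' @param circular optional logical vector of circularity flags.
#' @param n_cds optional predicted-CDS count, passed through.
#' @return A one-row data.frame of statistics.
#' @examples
#' compute_stats(data.frame(length = c(10, 8, 6, 4, 2)))$n50
#' @export
compute_stats <- function(contigs, circular = NULL, n_cds = NULL) {
  lens <- as_length_vector(contigs)
  if (length(lens) == 0L)
    stop("compute_stats: contig set must be non-empty")
  lens_sorted <- sort(lens, decreasing = TRUE)
  total <- sum(as.numeric(lens_sorted))
  cum <- cumsum(as.numeric(lens_sorted))
  n50 <- unname(lens_sorted[which(cum >= total / 2)[1L]])
  data.frame(
    n_contigs = length(lens),
    total_bp = total,
    bp_ge_50kbp = sum(as.numeric(lens[lens >= 50000])),
    largest_bp = max(lens),
    n50 = n50,
    n_ge_1mbp = sum(lens >= 1e6),
    n_circular = if (is.null(circular)) NA_integer_ else sum(circular),
    n_cds = if (is.null(n_cds)) NA_integer_ else n_cds
  )
}

#' Depth-based high-quality contig filter
#'
#' Keeps exactly the contigs whose mean read depth is strictly greater
#' than `min_depth` (default 5), preserving input order.
#'
#' @param contigs named character vector of sequences (names are contig
#'   ids), or a data.frame with a `contig_id` column.
#' @param depths data.frame with columns `contig_id` and `mean_depth`;
#'   every contig must have an entry.
#' @param min_depth strict lower depth bound.
#' @return The filtered subset of `contigs`, order preserved.
#' @export
filter_high_quality <- function(contigs, depths, min_depth = 5) {
  ids <- if (is.data.frame(contigs)) contigs$contig_id else names(contigs)
  if (is.null(ids))
    stop("filter_high_quality: contigs must carry contig ids")
  d <- depths$mean_depth[match(ids, depths$contig_id)]
  if (anyNA(d)) {
    missing <- ids[is.na(d)][1L]
    stop("filter_high_quality: no depth entry for contig '", missing, "'")
  }
  keep <- d > min_depth
  if (is.data.frame(contigs)) contigs[keep, , drop = FALSE]
  else contigs[keep]
}

#' Detect artificial low-complexity contigs
#'
#' Flags a contig as artificial when it contains a single-nucleotide run
#' of at least `min_run` bases, or when any one base makes up more than
#' `max_mono_run_frac` of the sequence.
#'
#' @param seq nucleotide string.
#' @param max_mono_run_frac maximum tolerated fraction of any single base.
#' @param min_run run length (bases) that triggers the flag.
#' @return `TRUE` when the contig looks artificial.
#' @export
detect_low_complexity <- function(seq, max_mono_run_frac = 0.5,
                                  min_run = 1000) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("detect_low_complexity: seq must be a non-empty string")
  raw <- charToRaw(seq)
  runs <- rle(as.integer(raw))
  if (max(runs$lengths) >= min_run) return(TRUE)
  freq <- tabulate(as.integer(raw), nbins = 255L)
  max(freq) / length(raw) > max_mono_run_frac
}
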