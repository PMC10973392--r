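# Readers and writers for the package's on-disk formats: FASTA (via
# Biostrings), flat TSV tables, and GFF3 (via rtracklayer).

#' Read contigs from a FASTA file
#'
#' @param path FASTA file.
#' @return Named character vector of upper-case sequences.
#' @export
read_contigs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write contigs to a FASTA file
#'
#' @param contigs named character vector of sequences.
#' @param path output FASTA file.
#' @export
write_contigs <- function(contigs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(contigs), path)
  invisible(path)
}

#' Write a 16S reference database as FASTA with lineage headers
#'
#' Headers carry the six-rank lineage, semicolon-delimited, after the
#' record id: `>T001 Phylum01;Class01_1;...;Species_001`.
#'
#' @param db reference data.frame as from [generate_reference_db()].
#' @param path output FASTA file.
#' @export
write_reference_fasta <- function(db, path) {
  seqs <- Biostrings::DNAStringSet(db$ssu_sequence)
  names(seqs) <- paste0(db$taxon_id, " ",
                        apply(db[, c("phylum", "class", "order", "family",
                                     "genus", "species")], 1L,
                              paste, collapse = ";"))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a 16S reference database from FASTA with lineage headers
#'
#' @param path FASTA file written by [write_reference_fasta()] (or any
#'   FASTA whose headers are `id phylum;class;order;family;genus;species`).
#' @return A reference data.frame.
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  lin <- sub("^\\S+\\s+", "", names(x))
  parts <- strsplit(lin, ";", fixed = TRUE)
  if (any(lengths(parts) != 6L))
    stop("read_reference_fasta: headers must carry a six-rank lineage")
  lin_df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(lin_df) <- c("phylum", "class", "order", "family", "genus", "species")
  out <- cbind(data.frame(taxon_id = ids), lin_df,
               data.frame(ssu_sequence = toupper(as.character(x))))
  rownames(out) <- NULL
  out
}

#' Read / write flat TSV tables
#'
#' Thin wrappers fixing the dialect (tab-separated, header, no quoting,
#' `NA` for missing) used by every table this package reads or writes.
#'
#' @param path TSV file.
#' @return `read_tsv_table()` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_tsv_table
#' @param x data.frame to write.
#' @export
write_tsv_table <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a gene annotation table as GFF3
#'
#' @param annotations annotation data.frame (`contig_id`, `gene_id`,
#'   `start`, `end`, `strand`, `label`, ...).
#' @param path output GFF3 file.
#' @export
write_annotation_gff3 <- function(annotations, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = annotations$contig_id,
    ranges = IRanges::IRanges(annotations$start, annotations$end),
    strand = annotations$strand)
  S4Vectors::mcols(gr)$ID <- annotations$gene_id
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$label <- annotations$label
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
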