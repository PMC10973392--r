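# Full-length 16S rRNA taxonomy: reference curation (length filter +
# greedy clustering), top-hit search with a coverage filter, tiered
# identity-based rank assignment, and depth-weighted community profiling.

#' Identity tiers mapping 16S identity to taxonomic rank
#'
#' The thresholds proxy taxonomic ranks: a gene at >= 97% identity to its
#' top hit is called at species level; lower identities resolve only a
#' higher rank and flag progressively deeper novelty.
#'
#' @return Named numeric vector of strictly decreasing thresholds
#'   (percent): species 97, genus 94.5, family 86.5, order 82, class 78.
#' @export
rank_tiers <- function() {
  c(species = 97, genus = 94.5, family = 86.5, order = 82, class = 78)
}

#' Curate a full-length 16S reference set
#'
#' Drops records with length <= `min_len`, then clusters the remainder
#' greedily: records are taken longest-first (ties broken by id); each
#' record either joins the first existing representative it matches at
#' >= `cluster_identity` or seeds a new cluster. The representatives are
#' returned.
#'
#' @param db reference data.frame with `taxon_id` and `ssu_sequence`
#'   columns.
#' @param min_len records of this length or shorter are removed (bases).
#' @param cluster_identity greedy clustering threshold (percent).
#' @return The subset of `db` rows that are cluster representatives, in
#'   seeding order.
#' @export
curate_reference_db <- function(db, min_len = 1400, cluster_identity = 97) {
  if (is.null(db) || nrow(db) == 0L)
    stop("curate_reference_db: records must be non-empty")
  keep <- nchar(db$ssu_sequence) > min_len
  db <- db[keep, , drop = FALSE]
  if (nrow(db) == 0L) {
    warning("curate_reference_db: all records removed by the length filter")
    return(db)
  }
  ord <- order(-nchar(db$ssu_sequence), db$taxon_id)
  db <- db[ord, , drop = FALSE]
  reps <- integer(0)
  for (i in seq_len(nrow(db))) {
    absorbed <- FALSE
    for (r in reps) {
      id <- pairwise_identity(db$ssu_sequence[i], db$ssu_sequence[r])$identity
      if (id >= cluster_identity) { absorbed <- TRUE; break }
    }
    if (!absorbed) reps <- c(reps, i)
  }
  out <- db[reps, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find the best reference hit for a 16S gene
#'
#' Aligns the gene to every curated reference record, removes alignments
#' with query coverage below `min_coverage`, and returns the highest
#' identity hit (ties broken by higher coverage, then lexicographic
#' reference id).
#'
#' @param gene a list or one-row data.frame with `sequence` (and
#'   optionally `gene_id`); the sequence must be >= 1400 bases.
#' @param db curated reference data.frame.
#' @param min_coverage minimum query coverage (percent).
#' @return A one-row data.frame (`ref_id`, `identity`, `query_coverage`
#'   plus the hit lineage), or `NULL` when no alignment passes coverage.
#' @export
search_top_hit <- function(gene, db, min_coverage = 95) {
  seq <- if (is.character(gene)) gene else gene$sequence
  if (nchar(seq) < 1400)
    stop("search_top_hit: gene shorter than 1400 bases")
  hits <- lapply(seq_len(nrow(db)), function(i) {
    al <- pairwise_identity(seq, db$ssu_sequence[i])
    data.frame(ref_id = db$taxon_id[i], identity = al$identity,
               query_coverage = al$query_coverage)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$query_coverage >= min_coverage, , drop = FALSE]
  if (nrow(hits) == 0L) return(NULL)
  hits <- hits[order(-hits$identity, -hits$query_coverage, hits$ref_id), ,
               drop = FALSE]
  top <- hits[1L, , drop = FALSE]
  lineage <- db[match(top$ref_id, db$taxon_id),
                c("phylum", "class", "order", "family", "genus", "species"),
                drop = FALSE]
  rownames(top) <- rownames(lineage) <- NULL
  cbind(top, lineage)
}

#' Assign a taxonomic rank tier from a 16S identity
#'
#' Tiers are lower-inclusive half-open intervals: identity >= 97 resolves
#' a known species; `[94.5, 97)` resolves genus (a novel species);
#' `[86.5, 94.5)` family (novel genus); `[82, 86.5)` order (novel family);
#' `[78, 82)` class (novel order); below 78 no rank is resolved and the
#' gene is flagged as a potential novel class.
#'
#' @param identity percent identity (vectorised), each in (0, 100].
#' @param tiers threshold vector as from [rank_tiers()].
#' @return A data.frame with columns `identity`, `resolved_rank` and
#'   `novelty_flag`.
#' @examples
#' assign_rank(c(98.2, 87.4, 77))
#' @export
assign_rank <- function(identity, tiers = rank_tiers()) {
  if (any(!is.finite(identity)) || any(identity <= 0) || any(identity > 100))
    stop("assign_rank: identity must be in (0, 100]")
  stopifnot(all(diff(tiers) < 0))
  breaks <- rev(unname(tiers)) # ascending: 78, 82, 86.5, 94.5, 97
  lvl <- findInterval(identity, breaks) # 0..5, lower-inclusive
  ranks <- c("unresolved", "class", "order", "family", "genus", "species")
  flags <- c("novel_class", "novel_order", "novel_family", "novel_genus",
             "novel_species", "known_species")
  data.frame(identity = identity,
             resolved_rank = ranks[lvl + 1L],
             novelty_flag = flags[lvl + 1L])
}

#' Extract annotated 16S genes from contigs
#'
#' Pulls every `SSU_RRNA` row of the annotation table whose gene is at
#' least `min_len` bases and whose contig has mean depth >= `min_depth`,
#' and extracts the gene sequence (reverse-complemented for minus-strand
#' genes).
#'
#' @param contigs named character vector of contig sequences.
#' @param annotations annotation data.frame.
#' @param depths depth data.frame (`contig_id`, `mean_depth`).
#' @param min_len minimum gene length (bases).
#' @param min_depth minimum contig depth (inclusive).
#' @return A data.frame: `gene_id`, `contig_id`, `sequence`, `length`,
#'   `contig_depth`.
#' @export
extract_ssu_genes <- function(contigs, annotations, depths,
                              min_len = 1400, min_depth = 5) {
  ssu <- annotations[annotations$label == "SSU_RRNA", , drop = FALSE]
  if (nrow(ssu) == 0L) {
    return(data.frame(gene_id = character(0), contig_id = character(0),
                      sequence = character(0), length = integer(0),
                      contig_depth = numeric(0)))
  }
  depth <- depths$mean_depth[match(ssu$contig_id, depths$contig_id)]
  if (anyNA(depth))
    stop("extract_ssu_genes: missing depth for contig '",
         ssu$contig_id[is.na(depth)][1L], "'")
  len <- ssu$end - ssu$start + 1L
  keep <- len >= min_len & depth >= min_depth
  ssu <- ssu[keep, , drop = FALSE]
  depth <- depth[keep]
  seqs <- vapply(seq_len(nrow(ssu)), function(i) {
    s <- substr(contigs[[ssu$contig_id[i]]], ssu$start[i], ssu$end[i])
    if (ssu$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(s)))
    s
  }, character(1))
  data.frame(gene_id = ssu$gene_id, contig_id = ssu$contig_id,
             sequence = seqs, length = nchar(seqs), contig_depth = depth)
}

#' Classify 16S genes against a curated reference database
#'
#' Runs [search_top_hit()] and [assign_rank()] for every gene. Genes with
#' no hit passing the coverage filter are reported with `NA` identity and
#' no rank.
#'
#' @param genes data.frame from [extract_ssu_genes()].
#' @param db curated reference data.frame.
#' @param tiers rank tier thresholds.
#' @param min_coverage minimum query coverage for a hit (percent).
#' @return A data.frame of per-gene assignments with top-hit lineage,
#'   identity, resolved rank and novelty flag.
#' @export
classify_ssu_genes <- function(genes, db, tiers = rank_tiers(),
                               min_coverage = 95) {
  rows <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- search_top_hit(genes[i, ], db, min_coverage = min_coverage)
    base <- data.frame(gene_id = genes$gene_id[i],
                       contig_id = genes$contig_id[i],
                       contig_depth = genes$contig_depth[i])
    if (is.null(hit)) {
      return(cbind(base, data.frame(
        ref_id = NA_character_, identity = NA_real_,
        query_coverage = NA_real_, species = NA_character_,
        genus = NA_character_, phylum = NA_character_,
        resolved_rank = NA_character_, novelty_flag = NA_character_)))
    }
    rank <- assign_rank(hit$identity, tiers)
    cbind(base, data.frame(
      ref_id = hit$ref_id, identity = hit$identity,
      query_coverage = hit$query_coverage, species = hit$species,
      genus = hit$genus, phylum = hit$phylum,
      resolved_rank = rank$resolved_rank,
      novelty_flag = rank$novelty_flag))
  })
  do.call(rbind, rows)
}

#' Depth-weighted community profile from 16S assignments
#'
#' Estimates species-level relative abundances from the depths of the
#' contigs carrying 16S genes. Only assignments at or above
#' `min_identity` (known species) enter the profile. Under `per_contig`
#' weighting (the default) a contig contributes its depth once per taxon
#' regardless of how many gene copies it carries; under `per_gene` every
#' gene copy contributes its contig's depth.
#'
#' @param assignments data.frame from [classify_ssu_genes()] (needs
#'   `species`, `contig_id`, `contig_depth`, `identity`).
#' @param weighting `"per_contig"` or `"per_gene"`.
#' @param min_identity species-level identity cutoff (percent).
#' @return A data.frame: `taxon`, `relative_abundance` (percent, summing
#'   to 100), `n_genes`, `n_contigs`, sorted by abundance.
#' @export
profile_community <- function(assignments,
                              weighting = c("per_contig", "per_gene"),
                              min_identity = 97) {
  weighting <- match.arg(weighting)
  ok <- !is.na(assignments$identity) & assignments$identity >= min_identity
  x <- assignments[ok, , drop = FALSE]
  if (nrow(x) == 0L) {
    warning("profile_community: no assignments at or above min_identity")
    return(data.frame(taxon = character(0), relative_abundance = numeric(0),
                      n_genes = integer(0), n_contigs = integer(0)))
  }
  if (anyNA(x$contig_depth))
    stop("profile_community: missing contig depth for gene '",
         x$gene_id[is.na(x$contig_depth)][1L], "'")
  if (weighting == "per_contig") {
    u <- unique(x[, c("species", "contig_id", "contig_depth")])
    w <- tapply(u$contig_depth, u$species, sum)
  } else {
    w <- tapply(x$contig_depth, x$species, sum)
  }
  n_genes <- tapply(x$gene_id, x$species, length)
  n_contigs <- tapply(x$contig_id, x$species,
                      function(v) length(unique(v)))
  taxa <- names(w)
  out <- data.frame(taxon = taxa,
                    relative_abundance = 100 * as.numeric(w) / sum(w),
                    n_genes = as.integer(n_genes[taxa]),
                    n_contigs = as.integer(n_contigs[taxa]))
  out <- out[order(-out$relative_abundance, out$taxon), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare two community profiles
#'
#' Takes the taxa above an abundance threshold in profile `b`, counts how
#' many are also present in profile `a`, and evaluates the combined
#' abundance of that taxon set in each profile separately.
#'
#' @param a,b community profiles (data.frames with `taxon` and
#'   `relative_abundance`), on the same taxonomy namespace.
#' @param threshold abundance threshold (percent) applied to `b`.
#' @return A list: `above_threshold` (taxa), `n_above_threshold`,
#'   `n_shared`, `combined_in_a`, `combined_in_b`.
#' @export
compare_profiles <- function(a, b, threshold = 1.0) {
  above <- b$taxon[b$relative_abundance > threshold]
  shared <- above[above %in% a$taxon]
  list(above_threshold = above,
       n_above_threshold = length(above),
       n_shared = length(shared),
       combined_in_a = sum(a$relative_abundance[a$taxon %in% above]),
       combined_in_b = sum(b$relative_abundance[b$taxon %in% above]))
}

#' Tier summary table of rank assignments
#'
#' Counts 16S genes and the contigs carrying them per identity tier,
#' mirroring the layout of a tiered-taxonomy summary table.
#'
#' @param assignments data.frame from [classify_ssu_genes()].
#' @return A data.frame: `threshold`, `resolved_rank`, `n_genes`,
#'   `n_contigs`.
#' @export
tier_summary <- function(assignments) {
  x <- assignments[!is.na(assignments$identity), , drop = FALSE]
  tiers <- rank_tiers()
  rows <- lapply(seq_along(tiers), function(i) {
    lo <- tiers[i]
    hi <- if (i == 1L) Inf else tiers[i - 1L]
    sel <- x$identity >= lo & x$identity < hi
    data.frame(threshold = unname(lo),
               resolved_rank = names(tiers)[i],
               n_genes = sum(sel),
               n_contigs = length(unique(x$contig_id[sel])))
  })
  below <- x$identity < tiers["class"]
  rows[[length(rows) + 1L]] <- data.frame(
    threshold = NA_real_, resolved_rank = "unresolved",
    n_genes = sum(below), n_contigs = length(unique(x$contig_id[below])))
  do.call(rbind, rows)
}
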