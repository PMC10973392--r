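# Ground-truthed synthetic community generator. Emits a contig set whose
# statistical structure (replicon classes, circular terminal overlaps,
# multi-copy 16S genes at controlled divergence, log-normal depths, marker
# annotations) matches what the downstream stages assume, together with a
# truth table for every contig.

# 16S templates are random sequences flanked by fixed conserved blocks so
# that ends-free alignment anchors; real secondary structure is not modeled.
conserved_blocks <- local({
  blocks <- NULL
  function() {
    if (is.null(blocks)) {
      blocks <<- with_seed(160816L, list(head = random_dna(100L),
                                         tail = random_dna(100L)))
    }
    blocks
  }
})

#' Generate a synthetic full-length 16S reference database
#'
#' Creates `n_taxa` reference taxa, each with a six-rank lineage
#' (phylum, class, order, family, genus, species) and a full-length
#' (1450-1600 bp) 16S rRNA sequence. Sequences are random cores flanked by
#' fixed conserved terminal blocks; any pair of species reaching 97%
#' identity is resampled, so distinct species are always below the
#' species-level identity threshold by construction. Lineages are built by
#' nested index paths, so two taxa sharing a genus necessarily share all
#' higher ranks.
#'
#' @param n_taxa number of reference taxa (>= 1).
#' @param seed integer seed; identical seeds give identical databases.
#' @return A data.frame with columns `taxon_id`, `phylum`, `class`,
#'   `order`, `family`, `genus`, `species` and `ssu_sequence`.
#' @examples
#' db <- generate_reference_db(3, seed = 1)
#' nchar(db$ssu_sequence)
#' @export
generate_reference_db <- function(n_taxa, seed = 1L) {
  if (!is.numeric(n_taxa) || length(n_taxa) != 1L || n_taxa < 1)
    stop("generate_reference_db: n_taxa must be a positive count")
  n_taxa <- as.integer(n_taxa)
  cb <- conserved_blocks()

  with_seed(seed, {
    n_phyla <- max(1L, min(n_taxa, ceiling(n_taxa / 6)))
    path <- cbind(
      sample.int(n_phyla, n_taxa, replace = TRUE),
      sample.int(2L, n_taxa, replace = TRUE),
      sample.int(2L, n_taxa, replace = TRUE),
      sample.int(2L, n_taxa, replace = TRUE),
      sample.int(2L, n_taxa, replace = TRUE)
    )
    lineage <- data.frame(
      phylum = sprintf("Phylum%02d", path[, 1]),
      class = sprintf("Class%02d_%d", path[, 1], path[, 2]),
      order = sprintf("Order%02d_%d_%d", path[, 1], path[, 2], path[, 3]),
      family = sprintf("Family%02d_%d_%d_%d",
                       path[, 1], path[, 2], path[, 3], path[, 4]),
      genus = sprintf("Genus%02d_%d_%d_%d_%d",
                      path[, 1], path[, 2], path[, 3], path[, 4], path[, 5]),
      species = sprintf("Species_%03d", seq_len(n_taxa))
    )

    make_seq <- function() {
      core_len <- sample(1250:1400, 1L)
      paste0(cb$head, random_dna(core_len), cb$tail)
    }
    seqs <- vapply(seq_len(n_taxa), function(i) make_seq(), character(1))

    # Rejection: distinct species must sit below the species threshold.
    if (n_taxa > 1L) {
      for (i in 2:n_taxa) {
        tries <- 0L
        repeat {
          ids <- vapply(seq_len(i - 1L), function(j) {
            pairwise_identity(seqs[i], seqs[j])$identity
          }, numeric(1))
          if (all(ids < 97)) break
          tries <- tries + 1L
          if (tries > 100L)
            stop("generate_reference_db: could not separate species")
          seqs[i] <- make_seq()
        }
      }
    }

    cbind(data.frame(taxon_id = sprintf("T%03d", seq_len(n_taxa))),
          lineage, data.frame(ssu_sequence = seqs))
  })
}

#' Mutate a sequence to a target percent identity
#'
#' Applies exactly `round((100 - target_identity)/100 * nchar(seq))`
#' substitutions at distinct positions (no indels), so the Hamming identity
#' to the input equals the target up to rounding of the substitution count.
#'
#' @param seq non-empty nucleotide string.
#' @param target_identity target identity in percent, in (70, 100].
#' @param seed integer seed.
#' @return The mutated sequence (same length as `seq`).
#' @examples
#' mutate_to_identity("ACGTACGTACGT", 100, seed = 1)
#' @export
mutate_to_identity <- function(seq, target_identity, seed = 1L) {
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) == 0L)
    stop("mutate_to_identity: seq must be a non-empty string")
  if (!is.numeric(target_identity) || target_identity <= 70 ||
      target_identity > 100)
    stop("mutate_to_identity: target_identity must be in (70, 100]")
  n <- nchar(seq)
  k <- round((100 - target_identity) / 100 * n)
  if (k == 0L) return(seq)
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    pos <- sample.int(n, k)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    for (p in pos) {
      chars[p] <- sample(setdiff(bases, chars[p]), 1L)
    }
    paste(chars, collapse = "")
  })
}

#' Configuration for the synthetic community generator
#'
#' The defaults emulate the structure of a PacBio long-read phyllosphere
#' assembly: a replicon mix dominated by small plasmids and phages with a
#' few closed chromosomes, log-normal contig depths, circular contigs
#' emitted with a duplicated terminal overlap, and multi-copy 16S genes at
#' controlled divergence from the reference database.
#'
#' @param n_contigs number of replicon contigs to emit.
#' @param replicon_mix named proportions over the six replicon classes;
#'   must sum to 1.
#' @param ssu_copy_range integer interval (min, max) of 16S copies per
#'   16S-bearing contig.
#' @param divergence_levels target 16S identities (percent, in (70, 100])
#'   sampled per planted gene copy.
#' @param divergence_weights sampling weights over `divergence_levels`.
#'   The defaults put about 69% of planted copies at species-level
#'   identity and spread the rest over the genus-to-class tiers, the
#'   proportions observed for full-length 16S genes in long-read
#'   phyllosphere assemblies.
#' @param depth_lognormal `c(mu, sigma)` of the log-normal depth model
#'   (depths floored at 0.1).
#' @param circular_fraction fraction of plasmid/phage/unclassified contigs
#'   emitted circular; chromosomes and megaplasmids are always circular.
#' @param terminal_overlap_len bases duplicated at the end of a circular
#'   contig's linear representation.
#' @param n_ssu_contigs additional linear chromosome-fragment contigs that
#'   carry 16S genes (truth class `unclassified`: they bear no replicon
#'   markers).
#' @param size_ranges named list of `c(min, max)` core lengths in bases per
#'   replicon class.
#' @param seed integer seed for the whole generation run.
#' @return A `community_config` list, validated.
#' @export
community_config <- function(
    n_contigs = 60L,
    replicon_mix = c(chromosome = 0.04, megaplasmid = 0.02,
                     repABC_plasmid = 0.29, putative_plasmid = 0.41,
                     bacteriophage = 0.20, unclassified = 0.04),
    ssu_copy_range = c(1L, 4L),
    divergence_levels = c(99.5, 98, 95.5, 90, 84, 80, 76),
    divergence_weights = c(0.35, 0.34, 0.09, 0.19, 0.024, 0.0015, 0.0045),
    depth_lognormal = c(mu = 2, sigma = 1),
    circular_fraction = 0.8,
    terminal_overlap_len = 2000L,
    n_ssu_contigs = 15L,
    size_ranges = list(chromosome = c(1e6, 5e6),
                       megaplasmid = c(1e6, 2e6),
                       repABC_plasmid = c(8e3, 3e5),
                       putative_plasmid = c(8e3, 3e5),
                       bacteriophage = c(1e4, 8e4),
                       unclassified = c(1e4, 1e5),
                       ssu_fragment = c(5e4, 3e5)),
    seed = 1L) {
  stopifnot(n_contigs >= 1, n_ssu_contigs >= 0)
  if (!setequal(names(replicon_mix), REPLICON_CLASSES))
    stop("community_config: replicon_mix must name all six replicon classes")
  if (abs(sum(replicon_mix) - 1) > 1e-9)
    stop("community_config: replicon_mix proportions must sum to 1")
  if (any(divergence_levels <= 70 | divergence_levels > 100))
    stop("community_config: divergence levels must be in (70, 100]")
  if (length(divergence_weights) != length(divergence_levels) ||
      any(divergence_weights < 0))
    stop("community_config: divergence_weights must match divergence_levels")
  if (terminal_overlap_len < 1)
    stop("community_config: terminal_overlap_len must be >= 1")
  if (circular_fraction < 0 || circular_fraction > 1)
    stop("community_config: circular_fraction must be in [0, 1]")
  stopifnot(length(ssu_copy_range) == 2L,
            ssu_copy_range[1] >= 1, ssu_copy_range[2] >= ssu_copy_range[1])
  structure(list(n_contigs = as.integer(n_contigs),
                 replicon_mix = replicon_mix[REPLICON_CLASSES],
                 ssu_copy_range = as.integer(ssu_copy_range),
                 divergence_levels = divergence_levels,
                 divergence_weights = divergence_weights /
                   sum(divergence_weights),
                 depth_lognormal = depth_lognormal,
                 circular_fraction = circular_fraction,
                 terminal_overlap_len = as.integer(terminal_overlap_len),
                 n_ssu_contigs = as.integer(n_ssu_contigs),
                 size_ranges = size_ranges,
                 seed = as.integer(seed)),
            class = "community_config")
}

# Marker gene sets planted per replicon class. repABC plasmids carry one
# or two repC genes (such plasmids are often annotated with more than one
# repC copy) and putative plasmids one to three plasmid-associated genes.
# Phage contigs additionally get a planted external phage score > 0.8; all
# other classes get scores well below the cutoff.
plant_markers <- function(klass, with_t4ss, t4ss_complete) {
  markers <- switch(klass,
    chromosome = "DNAA",
    megaplasmid = c("REPAB", "REPC", "PAR"),
    repABC_plasmid = c("REPAB", rep("REPC", sample(1:2, 1L))),
    putative_plasmid = sample(c("REPAB", "REPA", "TRAY", "PAR"),
                              sample(1:3, 1L)),
    bacteriophage = rep("PHAGE_STRUCTURAL", sample(2:4, 1L)),
    unclassified = character(0)
  )
  if (with_t4ss) {
    comp <- if (t4ss_complete) T4SS_COMPONENTS else
      sort(sample(T4SS_COMPONENTS, sample(3:10, 1L)))
    markers <- c(markers, comp)
  }
  markers
}

#' Generate a ground-truthed synthetic metagenome
#'
#' Emits contig sequences, a per-gene annotation table, per-contig mean
#' depths, planted external scores and a truth table. Circular contigs are
#' represented linearly with their first `terminal_overlap_len` bases
#' duplicated at the end. Chromosomes (and extra chromosome fragments)
#' carry planted 16S gene copies mutated to the configured divergence
#' levels; replicon marker genes follow each contig's true class, so the
#' downstream classifier can be scored against the truth table.
#'
#' @param config a [community_config()] object.
#' @param db reference database from [generate_reference_db()].
#' @return A list with elements `contigs` (named character vector of
#'   sequences), `annotations`, `depths`, `external_scores` and `truth`
#'   (data.frames).
#' @export
generate_community <- function(config, db) {
  if (!inherits(config, "community_config"))
    stop("generate_community: config must come from community_config()")
  if (is.null(db) || nrow(db) == 0L)
    stop("generate_community: reference database must be non-empty")

  with_seed(config$seed, {
    classes <- if (config$n_contigs == 1L) {
      sample(REPLICON_CLASSES, 1L, prob = config$replicon_mix)
    } else {
      sample(REPLICON_CLASSES, config$n_contigs, replace = TRUE,
             prob = config$replicon_mix)
    }
    spec_rows <- data.frame(
      contig_id = sprintf("CTG%04d", seq_len(config$n_contigs +
                                             config$n_ssu_contigs)),
      klass = c(classes, rep("unclassified", config$n_ssu_contigs)),
      is_fragment = c(rep(FALSE, config$n_contigs),
                      rep(TRUE, config$n_ssu_contigs))
    )
    n_all <- nrow(spec_rows)

    # Taxon assignment: chromosomes and fragments carry 16S genes.
    spec_rows$taxon_idx <- NA_integer_
    ssu_bearing <- spec_rows$klass == "chromosome" | spec_rows$is_fragment
    n_bear <- sum(ssu_bearing)
    if (n_bear > 0) {
      # cycle through the database so every taxon can appear
      idx <- rep_len(seq_len(nrow(db)), n_bear)
      spec_rows$taxon_idx[ssu_bearing] <- sample(idx)
    }

    ov <- config$terminal_overlap_len
    contigs <- character(n_all)
    truth <- vector("list", n_all)
    ann <- vector("list", n_all)
    scores <- vector("list", n_all)

    for (i in seq_len(n_all)) {
      row <- spec_rows[i, ]
      klass <- row$klass
      size_key <- if (row$is_fragment) "ssu_fragment" else klass
      rng <- config$size_ranges[[size_key]]
      core_len <- as.integer(round(runif(1, rng[1], rng[2])))

      circular <- if (row$is_fragment) FALSE
        else if (klass %in% c("chromosome", "megaplasmid")) TRUE
        else runif(1) < config$circular_fraction

      with_t4ss <- !row$is_fragment &&
        klass %in% c("repABC_plasmid", "putative_plasmid") && runif(1) < 0.25
      t4ss_complete <- runif(1) < 0.4
      markers <- plant_markers(klass, with_t4ss, t4ss_complete)

      # planted 16S copies
      ssu_seqs <- character(0)
      ssu_targets <- numeric(0)
      if (!is.na(row$taxon_idx)) {
        n_copies <- sample(config$ssu_copy_range[1]:config$ssu_copy_range[2],
                           1L)
        template <- db$ssu_sequence[row$taxon_idx]
        for (cpy in seq_len(n_copies)) {
          tgt <- sample(config$divergence_levels, 1L,
                        prob = config$divergence_weights)
          ssu_seqs <- c(ssu_seqs,
                        mutate_to_identity(template, tgt,
                                           seed = sample.int(2^30, 1L)))
          ssu_targets <- c(ssu_targets, tgt)
        }
      }

      # gene layout: markers + 16S + filler, sequential with random gaps
      n_marker <- length(markers)
      n_ssu <- length(ssu_seqs)
      gene_labels <- c(markers, rep("SSU_RRNA", n_ssu))
      gene_lens <- c(sample(600:1500, n_marker, replace = TRUE),
                     nchar(ssu_seqs))
      n_fill <- min(120L, max(4L, core_len %/% 5000L))
      budget <- core_len - sum(gene_lens) - 400L * (n_marker + n_ssu) - 500L
      n_fill <- max(0L, min(n_fill, budget %/% 2000L))
      gene_labels <- c(gene_labels, rep("OTHER", n_fill))
      gene_lens <- c(gene_lens, sample(600:1500, n_fill, replace = TRUE))
      need <- sum(gene_lens) + 400L * length(gene_lens) + 500L
      if (core_len < need) core_len <- need

      ord <- sample(seq_along(gene_labels))
      gene_labels <- gene_labels[ord]
      gene_lens <- gene_lens[ord]
      ssu_counter <- 0L # maps SSU rows back to planted sequences in order

      core <- random_dna(core_len)
      pos <- 101L
      rows <- vector("list", length(gene_labels))
      for (g in seq_along(gene_labels)) {
        gap <- sample(50:400, 1L)
        start <- pos + gap
        end <- start + gene_lens[g] - 1L
        pos <- end
        strand <- sample(c("+", "-"), 1L)
        if (gene_labels[g] == "SSU_RRNA") {
          ssu_counter <- ssu_counter + 1L
          planted <- ssu_seqs[ssu_counter]
          if (strand == "-")
            planted <- as.character(Biostrings::reverseComplement(
              Biostrings::DNAString(planted)))
          substr(core, start, end) <- planted
        }
        hit_species <- hit_genus <- hit_phylum <- NA_character_
        hit_id <- hit_cov <- NA_real_
        if (gene_labels[g] == "OTHER" && !is.na(row$taxon_idx) &&
            runif(1) < 0.4) {
          tax <- db[row$taxon_idx, ]
          hit_genus <- tax$genus
          hit_phylum <- tax$phylum
          hit_species <- paste0(tax$genus, "_sp", sample.int(5L, 1L))
          hit_id <- round(runif(1, 85, 99), 1)
          hit_cov <- round(runif(1, 85, 100), 1)
        }
        rows[[g]] <- data.frame(
          contig_id = row$contig_id,
          gene_id = sprintf("%s_g%03d", row$contig_id, g),
          start = start, end = end, strand = strand,
          label = gene_labels[g],
          hit_species = hit_species, hit_genus = hit_genus,
          hit_phylum = hit_phylum,
          identity = hit_id, coverage = hit_cov
        )
      }

      seq_out <- if (circular) paste0(core, substr(core, 1L, ov)) else core
      contigs[i] <- seq_out

      scores[[i]] <- data.frame(
        contig_id = row$contig_id,
        phage_score = if (klass == "bacteriophage")
          round(runif(1, 0.82, 0.99), 3) else round(runif(1, 0, 0.5), 3),
        viral_completeness = if (klass == "bacteriophage")
          round(runif(1, 14, 100), 1) else NA_real_,
        genome_completeness = if (klass == "chromosome")
          round(runif(1, 80, 100), 1) else NA_real_,
        contamination = if (klass == "chromosome")
          round(runif(1, 0, 5), 2) else NA_real_
      )
      truth[[i]] <- data.frame(
        contig_id = row$contig_id,
        true_class = klass,
        true_circular = circular,
        overlap_len = if (circular) ov else 0L,
        source_taxon = if (is.na(row$taxon_idx)) NA_character_
          else db$taxon_id[row$taxon_idx],
        source_species = if (is.na(row$taxon_idx)) NA_character_
          else db$species[row$taxon_idx],
        n_ssu = length(ssu_seqs),
        ssu_targets = paste(ssu_targets, collapse = ","),
        markers = paste(unique(markers), collapse = ",")
      )
      ann[[i]] <- do.call(rbind, rows)
    }

    depths <- data.frame(
      contig_id = spec_rows$contig_id,
      mean_depth = round(pmax(0.1, rlnorm(n_all,
                                          config$depth_lognormal[[1]],
                                          config$depth_lognormal[[2]])), 2)
    )
    names(contigs) <- spec_rows$contig_id
    list(contigs = contigs,
         annotations = do.call(rbind, ann),
         depths = depths,
         external_scores = do.call(rbind, scores),
         truth = do.call(rbind, truth))
  })
}
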