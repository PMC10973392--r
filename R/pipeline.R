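# End-to-end orchestration: QC -> circularity -> 16S taxonomy/profile ->
# replicon classification -> T4SS scoring, with every stage writing a
# documented TSV into the output directory.

#' Pipeline configuration
#'
#' Collects input paths and every stage threshold. All thresholds default
#' to the values used throughout the package documentation; each is a
#' plain list entry so a run log can record exactly what was used.
#'
#' @param contigs_fasta path to the contig FASTA.
#' @param depths_tsv path to the per-contig depth TSV (`contig_id`,
#'   `mean_depth`).
#' @param annotations_tsv path to the flat annotation TSV.
#' @param reference_fasta path to the 16S reference FASTA with lineage
#'   headers.
#' @param output_dir directory for stage outputs (created if needed).
#' @param external_scores_tsv optional per-contig score TSV.
#' @param amplicon_profile_tsv optional amplicon community profile TSV
#'   (`taxon`, `relative_abundance`).
#' @param min_depth strict depth cutoff of the high-quality filter.
#' @param min_depth_16s inclusive depth cutoff for 16S-bearing contigs.
#' @param min_overlap,max_overlap,max_mismatch_frac circularity scan
#'   parameters.
#' @param min_len_16s minimum 16S gene length (bases).
#' @param cluster_identity reference clustering threshold (percent).
#' @param min_coverage hit coverage filter (percent).
#' @param tiers rank tier thresholds.
#' @param min_fraction strict gene fraction of the contig-taxonomy rule.
#' @param replicon replicon decision-list thresholds.
#' @param profile_weighting abundance weighting mode.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(contigs_fasta, depths_tsv, annotations_tsv,
                            reference_fasta, output_dir,
                            external_scores_tsv = NULL,
                            amplicon_profile_tsv = NULL,
                            min_depth = 5, min_depth_16s = 5,
                            min_overlap = 1000, max_overlap = 50000,
                            max_mismatch_frac = 0.02,
                            min_len_16s = 1400, cluster_identity = 97,
                            min_coverage = 95, tiers = rank_tiers(),
                            min_fraction = 0.25,
                            replicon = replicon_params(),
                            profile_weighting = "per_contig") {
  cfg <- list(contigs_fasta = contigs_fasta, depths_tsv = depths_tsv,
              annotations_tsv = annotations_tsv,
              reference_fasta = reference_fasta, output_dir = output_dir,
              external_scores_tsv = external_scores_tsv,
              amplicon_profile_tsv = amplicon_profile_tsv,
              min_depth = min_depth, min_depth_16s = min_depth_16s,
              min_overlap = min_overlap, max_overlap = max_overlap,
              max_mismatch_frac = max_mismatch_frac,
              min_len_16s = min_len_16s,
              cluster_identity = cluster_identity,
              min_coverage = min_coverage, tiers = tiers,
              min_fraction = min_fraction, replicon = replicon,
              profile_weighting = profile_weighting)
  for (p in c("contigs_fasta", "depths_tsv", "annotations_tsv",
              "reference_fasta")) {
    if (!file.exists(cfg[[p]]))
      stop("pipeline_config: input file not found: ", cfg[[p]])
  }
  structure(cfg, class = "pipeline_config")
}

stage_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full contig-analysis pipeline
#'
#' Executes QC, circularity detection, 16S taxonomy and profiling,
#' replicon classification and T4SS scoring, writing each stage's table
#' into the configured output directory. Identical configuration and
#' inputs yield byte-identical outputs (no stage draws random numbers).
#'
#' @param config a [pipeline_config()] object.
#' @return (Invisibly) a run report list: stage tables, output paths and
#'   the thresholds used.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config"))
    stop("run_pipeline: config must come from pipeline_config()")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$output_dir, f)

  contigs <- read_contigs(config$contigs_fasta)
  depths <- read_tsv_table(config$depths_tsv)
  annotations <- read_tsv_table(config$annotations_tsv)
  external_scores <- if (!is.null(config$external_scores_tsv))
    read_tsv_table(config$external_scores_tsv) else NULL

  # --- stage 1: assembly QC ------------------------------------------------
  artificial <- vapply(contigs, detect_low_complexity, logical(1))
  if (any(artificial))
    stage_log("qc", sum(artificial), " artificial contig(s) removed")
  contigs <- contigs[!artificial]
  hq <- filter_high_quality(contigs, depths, min_depth = config$min_depth)
  stage_log("qc", length(contigs), " contigs in, ", length(hq),
            " high-quality (depth > ", config$min_depth, ")")

  # --- stage 2: circularity ------------------------------------------------
  circ <- detect_circular_contigs(hq, min_overlap = config$min_overlap,
                                  max_overlap = config$max_overlap,
                                  max_mismatch_frac =
                                    config$max_mismatch_frac)
  stage_log("circular", sum(circ$is_circular), " of ", nrow(circ),
            " high-quality contigs circular")
  trimmed <- hq
  for (i in which(circ$is_circular)) {
    trimmed[[circ$contig_id[i]]] <- circularize(
      hq[[circ$contig_id[i]]],
      list(is_circular = TRUE, overlap_len = circ$overlap_len[i]))
  }
  write_tsv_table(circ[circ$is_circular,
                       c("contig_id", "overlap_len", "trimmed_length")],
                  out("circular_contigs.tsv"))
  write_contigs(trimmed[circ$contig_id[circ$is_circular]],
                out("circular_trimmed.fasta"))

  stats_all <- compute_stats(contigs)
  stats_hq <- compute_stats(
    hq, circular = circ$is_circular[match(names(hq), circ$contig_id)])
  stats_tbl <- cbind(data.frame(set = c("all", "high_quality")),
                     rbind(stats_all, stats_hq))
  rownames(stats_tbl) <- NULL
  write_tsv_table(stats_tbl, out("assembly_stats.tsv"))

  # --- stage 3: 16S taxonomy and profile -----------------------------------
  reference <- read_reference_fasta(config$reference_fasta)
  curated <- curate_reference_db(reference, min_len = config$min_len_16s,
                                 cluster_identity = config$cluster_identity)
  stage_log("ssu", nrow(curated), " curated reference records (from ",
            nrow(reference), ")")
  genes <- extract_ssu_genes(hq, annotations, depths,
                             min_len = config$min_len_16s,
                             min_depth = config$min_depth_16s)
  empty_ann <- nrow(annotations) == 0L
  if (nrow(genes) == 0L) {
    warning("run_pipeline: no eligible 16S genes; profile is empty")
    assignments <- data.frame()
    profile <- data.frame(taxon = character(0),
                          relative_abundance = numeric(0),
                          n_genes = integer(0), n_contigs = integer(0))
  } else {
    assignments <- classify_ssu_genes(genes, curated, tiers = config$tiers,
                                      min_coverage = config$min_coverage)
    profile <- suppressWarnings(
      profile_community(assignments, weighting = config$profile_weighting))
    write_tsv_table(assignments, out("ssu_assignments.tsv"))
    write_tsv_table(tier_summary(assignments), out("ssu_tier_summary.tsv"))
  }
  write_tsv_table(profile, out("community_profile.tsv"))
  stage_log("ssu", nrow(genes), " 16S genes, ",
            nrow(profile), " species in profile")

  comparison <- NULL
  if (!is.null(config$amplicon_profile_tsv)) {
    amplicon <- read_tsv_table(config$amplicon_profile_tsv)
    comparison <- compare_profiles(profile, amplicon)
    stage_log("ssu", comparison$n_shared, " of ",
              comparison$n_above_threshold,
              " abundant amplicon species also in the metagenome profile")
  }

  # --- stage 4: replicon classification ------------------------------------
  contig_df <- data.frame(
    contig_id = names(hq), length = nchar(hq),
    circular = circ$is_circular[match(names(hq), circ$contig_id)])
  fv <- build_feature_table(annotations, contig_df, external_scores)
  calls <- classify_replicons(fv, config$replicon)
  taxon_calls <- vapply(names(hq), function(id) {
    rows_i <- annotations[annotations$contig_id == id, , drop = FALSE]
    if (nrow(rows_i) == 0L) return(NA_character_)
    tc <- assign_contig_taxonomy(rows_i, min_fraction = config$min_fraction)
    if (is.null(tc)) NA_character_ else tc$name
  }, character(1))
  calls$taxon_call <- unname(taxon_calls)
  write_tsv_table(calls, out("replicon_calls.tsv"))
  counts <- table(factor(calls$klass, levels = REPLICON_CLASSES))
  stage_log("classify", paste(names(counts), as.integer(counts),
                              sep = "=", collapse = ", "))

  # --- stage 5: T4SS scoring -----------------------------------------------
  t4ss <- t4ss_report(annotations, contig_ids = names(hq))
  write_tsv_table(t4ss, out("t4ss_report.tsv"))
  stage_log("t4ss", sum(t4ss$status %in% c("complete", "nearly_complete")),
            " contig(s) with complete/nearly complete VirB/VirD4 systems")

  report <- list(stats = stats_tbl, circular = circ,
                 assignments = assignments, profile = profile,
                 profile_comparison = comparison, replicon_calls = calls,
                 t4ss = t4ss, class_counts = counts,
                 thresholds = config[setdiff(names(config),
                                             c("tiers", "replicon"))],
                 tiers = config$tiers, replicon_params = config$replicon,
                 version = as.character(packageVersion("phyllotig")))
  if (empty_ann)
    stage_log("run", "annotation table was empty; ",
              "all contigs unclassified and profile empty")
  invisible(report)
}

#' Generate a small self-contained demo dataset
#'
#' Writes a synthetic community (contigs, depths, annotations, external
#' scores, truth, reference database) scaled to run end to end in well
#' under two minutes on one CPU, runs the pipeline on it, and records MD5
#' checksums of all inputs and outputs so reruns can be verified
#' byte-for-byte.
#'
#' @param seed integer seed.
#' @param outdir writable output directory.
#' @return (Invisibly) a list with `paths` (input files), `config` (the
#'   pipeline configuration used), `report` (the pipeline run report) and
#'   `checksums` (data.frame of file MD5s).
#' @export
make_demo <- function(seed, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir))
    stop("make_demo: cannot create output directory ", outdir)
  seeds <- split_seed(seed, 2L)
  db <- generate_reference_db(8, seed = seeds[1])
  cfg <- community_config(
    n_contigs = 25L,
    size_ranges = list(chromosome = c(1e6, 1.3e6),
                       megaplasmid = c(1e6, 1.1e6),
                       repABC_plasmid = c(8e3, 6e4),
                       putative_plasmid = c(8e3, 6e4),
                       bacteriophage = c(1e4, 5e4),
                       unclassified = c(1e4, 5e4),
                       ssu_fragment = c(3e4, 8e4)),
    n_ssu_contigs = 8L,
    depth_lognormal = c(mu = 3, sigma = 0.6),
    seed = seeds[2])
  com <- generate_community(cfg, db)

  paths <- list(
    contigs = file.path(outdir, "contigs.fasta"),
    depths = file.path(outdir, "depths.tsv"),
    annotations = file.path(outdir, "annotations.tsv"),
    annotations_gff3 = file.path(outdir, "annotations.gff3"),
    external_scores = file.path(outdir, "external_scores.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    reference = file.path(outdir, "reference_db.fasta"))
  write_contigs(com$contigs, paths$contigs)
  write_tsv_table(com$depths, paths$depths)
  write_tsv_table(com$annotations, paths$annotations)
  write_annotation_gff3(com$annotations, paths$annotations_gff3)
  write_tsv_table(com$external_scores, paths$external_scores)
  write_tsv_table(com$truth, paths$truth)
  write_reference_fasta(db, paths$reference)

  pcfg <- pipeline_config(
    contigs_fasta = paths$contigs, depths_tsv = paths$depths,
    annotations_tsv = paths$annotations,
    reference_fasta = paths$reference,
    external_scores_tsv = paths$external_scores,
    output_dir = file.path(outdir, "results"))
  report <- run_pipeline(pcfg)

  files <- c(unlist(paths),
             list.files(file.path(outdir, "results"), full.names = TRUE))
  sums <- tools::md5sum(files)
  checksums <- data.frame(file = basename(names(sums)),
                          md5 = unname(sums))
  write_tsv_table(checksums, file.path(outdir, "checksums.tsv"))
  invisible(list(paths = paths, config = pcfg, report = report,
                 checksums = checksums, truth = com$truth))
}

#' Stacked-bar plot of community profiles
#'
#' @param profiles named list of community profiles (one bar per
#'   profile).
#' @param top number of most abundant taxa shown individually; the rest
#'   are pooled as "other".
#' @export
plot_community_profiles <- function(profiles, top = 10) {
  taxa <- unique(unlist(lapply(profiles, function(p) p$taxon)))
  mat <- vapply(profiles, function(p) {
    v <- setNames(rep(0, length(taxa)), taxa)
    v[p$taxon] <- p$relative_abundance
    v
  }, numeric(length(taxa)))
  keep <- order(-rowSums(mat))[seq_len(min(top, nrow(mat)))]
  other <- colSums(mat[-keep, , drop = FALSE])
  m <- rbind(mat[keep, , drop = FALSE], other = other)
  graphics::barplot(m, col = grDevices::hcl.colors(nrow(m), "Spectral"),
                    legend.text = rownames(m),
                    ylab = "relative abundance (%)")
  invisible(m)
}
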