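# Rule-based classification of contigs into chromosome, megaplasmid,
# repABC plasmid, putative plasmid, bacteriophage or unclassified, plus
# contig-level genus assignment and VirB/VirD4 T4SS completeness and
# arrangement scoring.

#' Default thresholds of the replicon decision list
#'
#' @param min_chromosome_bp minimum length (bases) for the
#'   chromosome/megaplasmid rules.
#' @param min_completeness genome completeness (percent) accepted in place
#'   of a dnaA gene for the chromosome rule.
#' @param phage_score_cutoff strict phage-score cutoff.
#' @return A named list of thresholds.
#' @export
replicon_params <- function(min_chromosome_bp = 1e6, min_completeness = 50,
                            phage_score_cutoff = 0.8) {
  list(min_chromosome_bp = min_chromosome_bp,
       min_completeness = min_completeness,
       phage_score_cutoff = phage_score_cutoff)
}

#' Reduce gene annotations to a per-contig feature vector
#'
#' Marker booleans are existence checks over annotation labels;
#' `n_virB_components` counts the distinct VirB components present.
#' External per-contig scores (phage score, viral completeness, genome
#' completeness, contamination) pass through when supplied.
#'
#' @param annotations annotation data.frame (all contigs or one).
#' @param contig a list or one-row data.frame with `contig_id`, `length`
#'   and `circular`.
#' @param external_scores optional data.frame keyed by `contig_id` with
#'   any of `phage_score`, `viral_completeness`, `genome_completeness`,
#'   `contamination`.
#' @return A one-row data.frame feature vector.
#' @export
build_features <- function(annotations, contig, external_scores = NULL) {
  rows <- annotations[annotations$contig_id == contig$contig_id, ,
                      drop = FALSE]
  bad <- !(rows$label %in% ANNOTATION_LABELS)
  if (any(bad))
    stop("build_features: unknown label '", rows$label[bad][1L],
         "' in row for gene '", rows$gene_id[bad][1L], "'")
  labels <- rows$label
  virb <- unique(labels[labels %in% paste0("VIRB", 1:11)])
  ext <- list(phage_score = NA_real_, viral_completeness = NA_real_,
              genome_completeness = NA_real_, contamination = NA_real_)
  if (!is.null(external_scores)) {
    j <- match(contig$contig_id, external_scores$contig_id)
    if (!is.na(j)) {
      for (k in names(ext)) {
        if (k %in% names(external_scores)) ext[[k]] <- external_scores[[k]][j]
      }
    }
  }
  data.frame(
    contig_id = contig$contig_id,
    length = contig$length,
    circular = isTRUE(contig$circular),
    has_dnaA = "DNAA" %in% labels,
    has_repA = "REPA" %in% labels,
    has_repC = "REPC" %in% labels,
    has_repAB = "REPAB" %in% labels,
    has_traY = "TRAY" %in% labels,
    has_par = "PAR" %in% labels,
    has_phage_structural = "PHAGE_STRUCTURAL" %in% labels,
    n_virB_components = length(virb),
    has_virD4 = "VIRD4" %in% labels,
    phage_score = ext$phage_score,
    viral_completeness = ext$viral_completeness,
    genome_completeness = ext$genome_completeness,
    contamination = ext$contamination
  )
}

#' Build the feature table for a whole contig set
#'
#' @param annotations annotation data.frame.
#' @param contig_df data.frame with `contig_id`, `length`, `circular`.
#' @param external_scores optional per-contig score table.
#' @return A data.frame with one feature-vector row per contig.
#' @export
build_feature_table <- function(annotations, contig_df,
                                external_scores = NULL) {
  rows <- lapply(seq_len(nrow(contig_df)), function(i) {
    build_features(annotations, contig_df[i, ], external_scores)
  })
  do.call(rbind, rows)
}

#' Classify a contig by the replicon decision list
#'
#' An ordered decision list, first match wins:
#' 1. circular, >= 1 Mbp, with dnaA (or genome completeness >= 50%) and no
#'    plasmid-type replication gene (repA/repC/repAB) -> chromosome;
#' 2. circular, >= 1 Mbp, with plasmid-type replication -> megaplasmid;
#' 3. phage score > 0.8 -> bacteriophage;
#' 4. repC present -> repABC plasmid;
#' 5. repAB, repA or TraY present, or partitioning or VirB genes without
#'    phage structural genes -> putative plasmid;
#' 6. otherwise unclassified.
#' The evidence field lists every satisfied predicate of the fired rule.
#'
#' @param fv a one-row feature vector from [build_features()].
#' @param params thresholds from [replicon_params()].
#' @return A list: `contig_id`, `klass`, `evidence` (character vector).
#' @export
classify_replicon <- function(fv, params = replicon_params()) {
  plasmid_rep <- isTRUE(fv$has_repA) || isTRUE(fv$has_repC) ||
    isTRUE(fv$has_repAB)
  big <- isTRUE(fv$circular) && fv$length >= params$min_chromosome_bp
  complete <- !is.na(fv$genome_completeness) &&
    fv$genome_completeness >= params$min_completeness
  phage <- !is.na(fv$phage_score) &&
    fv$phage_score > params$phage_score_cutoff

  if (big && (isTRUE(fv$has_dnaA) || complete) && !plasmid_rep) {
    ev <- c("circular", "length_ge_min_chromosome",
            if (isTRUE(fv$has_dnaA)) "has_dnaA",
            if (complete) "genome_completeness_ge_min",
            "no_plasmid_replication")
    return(list(contig_id = fv$contig_id, klass = "chromosome",
                evidence = ev))
  }
  if (big && plasmid_rep) {
    ev <- c("circular", "length_ge_min_chromosome",
            if (isTRUE(fv$has_repA)) "has_repA",
            if (isTRUE(fv$has_repC)) "has_repC",
            if (isTRUE(fv$has_repAB)) "has_repAB")
    return(list(contig_id = fv$contig_id, klass = "megaplasmid",
                evidence = ev))
  }
  if (phage) {
    return(list(contig_id = fv$contig_id, klass = "bacteriophage",
                evidence = "phage_score_gt_cutoff"))
  }
  if (isTRUE(fv$has_repC)) {
    return(list(contig_id = fv$contig_id, klass = "repABC_plasmid",
                evidence = "has_repC"))
  }
  ev <- c(if (isTRUE(fv$has_repAB)) "has_repAB",
          if (isTRUE(fv$has_repA)) "has_repA",
          if (isTRUE(fv$has_traY)) "has_traY",
          if (isTRUE(fv$has_par) && !isTRUE(fv$has_phage_structural))
            "has_par_no_phage_genes",
          if (fv$n_virB_components >= 1 && !isTRUE(fv$has_phage_structural))
            "virB_no_phage_genes")
  if (length(ev) > 0) {
    return(list(contig_id = fv$contig_id, klass = "putative_plasmid",
                evidence = ev))
  }
  list(contig_id = fv$contig_id, klass = "unclassified",
       evidence = character(0))
}

#' Classify every contig of a feature table
#'
#' @param fv_table feature table from [build_feature_table()].
#' @param params thresholds from [replicon_params()].
#' @return A data.frame: `contig_id`, `klass`, `evidence`
#'   (semicolon-joined).
#' @export
classify_replicons <- function(fv_table, params = replicon_params()) {
  rows <- lapply(seq_len(nrow(fv_table)), function(i) {
    call <- classify_replicon(fv_table[i, ], params)
    data.frame(contig_id = call$contig_id, klass = call$klass,
               evidence = paste(call$evidence, collapse = ";"))
  })
  do.call(rbind, rows)
}

#' Contig-level genus assignment by gene-hit consensus
#'
#' A genus is assigned only when the genes hitting it (at identity and
#' coverage at least `min_identity` / `min_coverage`) strictly exceed
#' `min_fraction` of all annotated genes on the contig, and every
#' qualifying hit on the contig comes from a single phylum. Ambiguity
#' (two phyla, or two genera tied for the top count) leaves the contig
#' unassigned.
#'
#' @param annotations annotation rows for one contig (must be non-empty).
#' @param min_fraction strict fraction of all genes required ("exceeding
#'   one-fourth" by default).
#' @param min_identity,min_coverage hit quality filters (percent).
#' @return A list (`rank`, `name`, `n_support`, `n_genes`) or `NULL`.
#' @export
assign_contig_taxonomy <- function(annotations, min_fraction = 0.25,
                                   min_identity = 80, min_coverage = 80) {
  n_genes <- nrow(annotations)
  if (is.null(n_genes) || n_genes == 0L)
    stop("assign_contig_taxonomy: contig has no annotated genes")
  q <- annotations[
    !is.na(annotations$hit_genus) &
      !is.na(annotations$identity) & annotations$identity >= min_identity &
      !is.na(annotations$coverage) & annotations$coverage >= min_coverage, ,
    drop = FALSE]
  if (nrow(q) == 0L) return(NULL)
  if (length(unique(q$hit_phylum)) != 1L) return(NULL)
  counts <- sort(table(q$hit_genus), decreasing = TRUE)
  if (length(counts) > 1L && counts[1L] == counts[2L]) return(NULL)
  if (counts[1L] <= min_fraction * n_genes) return(NULL)
  list(rank = "genus", name = names(counts)[1L],
       n_support = as.integer(counts[1L]), n_genes = n_genes)
}

#' Score VirB/VirD4 T4SS completeness on a contig
#'
#' The reference system has 11 VirB components plus VirD4. Status:
#' `complete` with all 12 distinct components, `nearly_complete` with
#' 10-11, `partial` with 1-9, `absent` with none.
#'
#' @param annotations annotation rows for one contig.
#' @return A list: `present` (distinct components), `status`,
#'   `duplicated` (components seen more than once), `missing`.
#' @export
score_t4ss <- function(annotations) {
  comp <- annotations$label[annotations$label %in% T4SS_COMPONENTS]
  present <- intersect(T4SS_COMPONENTS, comp) # reference order
  n <- length(present)
  status <- if (n == 12L) "complete" else if (n >= 10L) "nearly_complete"
    else if (n >= 1L) "partial" else "absent"
  tab <- table(comp)
  list(present = present, status = status,
       duplicated = intersect(T4SS_COMPONENTS, names(tab)[tab > 1L]),
       missing = setdiff(T4SS_COMPONENTS, present))
}

is_subsequence <- function(x, ref) {
  if (length(x) == 0L) return(TRUE)
  j <- 1L
  for (r in ref) {
    if (x[j] == r) {
      j <- j + 1L
      if (j > length(x)) return(TRUE)
    }
  }
  FALSE
}

#' Compare an observed T4SS gene arrangement with the reference operon
#'
#' The reference arrangement is VirB1..VirB11 followed by VirD4. Reports
#' duplicated and missing components and whether the de-duplicated
#' observed order is a subsequence of the circularly rotated reference
#' (both orientations are checked, as the operon may sit on either strand
#' of a circular replicon).
#'
#' @param observed character vector of components in positional order on
#'   the contig.
#' @param reference the reference arrangement.
#' @return A list: `duplicated`, `missing`, `observed_order`
#'   (de-duplicated), `matches_reference_order` (logical).
#' @export
arrangement_compare <- function(observed, reference = T4SS_COMPONENTS) {
  stopifnot(all(observed %in% reference))
  dup <- intersect(reference, unique(observed[duplicated(observed)]))
  missing <- setdiff(reference, observed)
  dedup <- observed[!duplicated(observed)]
  n <- length(reference)
  ok <- FALSE
  for (rot in seq_len(n) - 1L) {
    r <- c(reference[(rot + 1L):n], reference[seq_len(rot)])
    if (is_subsequence(dedup, r) || is_subsequence(dedup, rev(r))) {
      ok <- TRUE
      break
    }
  }
  list(duplicated = dup, missing = missing, observed_order = dedup,
       matches_reference_order = ok)
}

#' T4SS report for a whole contig set
#'
#' One row per contig with component presence, completeness status and
#' whether the observed arrangement follows the reference operon order.
#'
#' @param annotations annotation data.frame.
#' @param contig_ids contigs to report (default: all annotated).
#' @return A data.frame, one row per contig.
#' @export
t4ss_report <- function(annotations, contig_ids = NULL) {
  if (is.null(contig_ids)) contig_ids <- unique(annotations$contig_id)
  rows <- lapply(contig_ids, function(id) {
    rows_i <- annotations[annotations$contig_id == id, , drop = FALSE]
    sc <- score_t4ss(rows_i)
    t4 <- rows_i[rows_i$label %in% T4SS_COMPONENTS, , drop = FALSE]
    t4 <- t4[order(t4$start), , drop = FALSE]
    arr <- arrangement_compare(t4$label)
    data.frame(contig_id = id,
               n_components = length(sc$present),
               status = sc$status,
               present = paste(sc$present, collapse = ","),
               duplicated = paste(sc$duplicated, collapse = ","),
               missing = paste(sc$missing, collapse = ","),
               matches_reference_order = arr$matches_reference_order)
  })
  do.call(rbind, rows)
}
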