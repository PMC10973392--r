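ann_row <- function(contig, label, gene = NULL, start = 1, end = 1000,
                    genus = NA, phylum = NA, identity = NA, coverage = NA) {
  data.frame(contig_id = contig,
             gene_id = if (is.null(gene)) paste0(contig, "_", label) else gene,
             start = start, end = end, strand = "+", label = label,
             hit_species = NA_character_, hit_genus = genus,
             hit_phylum = phylum, identity = identity, coverage = coverage)
}

fv_of <- function(labels, contig_id = "c1", length = 50000, circular = TRUE,
                  scores = NULL) {
  ann <- do.call(rbind, lapply(seq_along(labels), function(i) {
    ann_row(contig_id, labels[i], gene = sprintf("%s_g%d", contig_id, i),
            start = i * 2000, end = i * 2000 + 999)
  }))
  if (length(labels) == 0L) ann <- ann_row(contig_id, "OTHER")[0, ]
  build_features(ann, list(contig_id = contig_id, length = length,
                           circular = circular), scores)
}

test_that("feature vectors are existence summaries of the labels", {
  fv <- fv_of(c("REPC", "OTHER"))
  expect_true(fv$has_repC)
  expect_false(any(fv$has_dnaA, fv$has_repA, fv$has_repAB, fv$has_traY,
                   fv$has_par, fv$has_phage_structural, fv$has_virD4))
  full <- fv_of(c(paste0("VIRB", 1:11), "VIRD4"))
  expect_equal(full$n_virB_components, 11L)
  expect_true(full$has_virD4)
  empty <- fv_of(character(0))
  expect_equal(empty$n_virB_components, 0L)
  expect_false(any(unlist(empty[, grep("^has_", names(empty))])))
  bad <- ann_row("c1", "NOT_A_LABEL")
  expect_error(build_features(bad, list(contig_id = "c1", length = 1,
                                        circular = FALSE)),
               "NOT_A_LABEL")
})

test_that("the decision list classifies the canonical cases", {
  scores <- data.frame(contig_id = "c1", phage_score = NA_real_,
                       genome_completeness = 95)
  chrom <- classify_replicon(fv_of("DNAA", length = 4.3e6, circular = TRUE,
                                   scores = scores))
  expect_equal(chrom$klass, "chromosome")
  expect_true("has_dnaA" %in% chrom$evidence)

  repabc <- classify_replicon(fv_of("REPC", length = 120e3, circular = TRUE))
  expect_equal(repabc$klass, "repABC_plasmid")

  phage <- classify_replicon(fv_of("PHAGE_STRUCTURAL", length = 45e3,
                                   circular = FALSE,
                                   scores = data.frame(contig_id = "c1",
                                                       phage_score = 0.92)))
  expect_equal(phage$klass, "bacteriophage")

  none <- classify_replicon(fv_of(character(0), length = 30e3,
                                  circular = TRUE))
  expect_equal(none$klass, "unclassified")
  expect_length(none$evidence, 0L)

  put <- classify_replicon(fv_of(c("TRAY", "OTHER"), length = 60e3,
                                 circular = FALSE))
  expect_equal(put$klass, "putative_plasmid")
  # partitioning or VirB genes alongside phage structural genes do not
  # promote a contig to putative plasmid
  parphage <- classify_replicon(fv_of(c("PAR", "PHAGE_STRUCTURAL"),
                                      length = 40e3, circular = FALSE))
  expect_equal(parphage$klass, "unclassified")
})

test_that("megaplasmid precedence beats the phage score rule", {
  fv <- fv_of("REPC", length = 1.4e6, circular = TRUE,
              scores = data.frame(contig_id = "c1", phage_score = 0.95))
  expect_equal(classify_replicon(fv)$klass, "megaplasmid")
})

test_that("every feature vector maps to exactly one class", {
  set.seed(50)
  for (i in 1:200) {
    labels <- sample(ANNOTATION_LABELS, sample(0:6, 1), replace = TRUE)
    fv <- fv_of(labels, length = sample(c(2e4, 8e5, 2e6), 1),
                circular = sample(c(TRUE, FALSE), 1),
                scores = data.frame(contig_id = "c1",
                                    phage_score = runif(1)))
    call <- classify_replicon(fv)
    expect_true(call$klass %in% REPLICON_CLASSES)
    expect_length(call$klass, 1L)
    if (call$klass != "unclassified") expect_gt(length(call$evidence), 0L)
  }
})

taxonomy_fixture <- function(n_hits, n_total, phyla = "P1") {
  hits <- do.call(rbind, lapply(seq_len(n_hits), function(i) {
    ann_row("c1", "OTHER", gene = paste0("g", i), genus = "G",
            phylum = phyla[((i - 1) %% length(phyla)) + 1],
            identity = 90, coverage = 90)
  }))
  rest <- do.call(rbind, lapply(seq_len(n_total - n_hits), function(i) {
    ann_row("c1", "OTHER", gene = paste0("h", i))
  }))
  rbind(hits, rest)
}

test_that("contig taxonomy requires strictly more than one fourth of genes", {
  expect_equal(assign_contig_taxonomy(taxonomy_fixture(30, 100))$name, "G")
  expect_null(assign_contig_taxonomy(taxonomy_fixture(25, 100)))
  expect_equal(assign_contig_taxonomy(taxonomy_fixture(26, 100))$name, "G")
  expect_null(assign_contig_taxonomy(
    taxonomy_fixture(40, 100, phyla = c("P1", "P2"))))
  expect_error(assign_contig_taxonomy(taxonomy_fixture(1, 1)[0, ]),
               "no annotated genes")
})

test_that("contig taxonomy ignores row order and counts null hits only in the denominator", {
  x <- taxonomy_fixture(30, 100)
  shuffled <- x[sample(nrow(x)), ]
  expect_identical(assign_contig_taxonomy(x),
                   assign_contig_taxonomy(shuffled))
  # dropping null-hit genes shrinks the denominator and can enable a call
  y <- taxonomy_fixture(26, 110)
  expect_null(assign_contig_taxonomy(y))
  expect_equal(assign_contig_taxonomy(y[1:100, ])$name, "G")
})

test_that("T4SS completeness follows the component count", {
  all12 <- fv_ann <- do.call(rbind, lapply(seq_along(T4SS_COMPONENTS),
    function(i) ann_row("c1", T4SS_COMPONENTS[i], gene = paste0("t", i))))
  expect_equal(score_t4ss(all12)$status, "complete")
  expect_equal(score_t4ss(all12[1:10, ])$status, "nearly_complete")
  expect_equal(score_t4ss(all12[1:9, ])$status, "partial")
  none <- score_t4ss(all12[0, ])
  expect_equal(none$status, "absent")
  expect_length(none$missing, 12L)
  dup <- score_t4ss(rbind(all12, all12[3, ]))
  expect_equal(dup$duplicated, "VIRB3")
  expect_equal(dup$status, "complete")
})

test_that("arrangement comparison detects order, loss and duplication", {
  ref <- T4SS_COMPONENTS
  exact <- arrangement_compare(ref)
  expect_true(exact$matches_reference_order)
  expect_length(exact$duplicated, 0L)
  expect_length(exact$missing, 0L)

  no5 <- arrangement_compare(setdiff(ref, "VIRB5"))
  expect_equal(no5$missing, "VIRB5")
  expect_true(no5$matches_reference_order)

  rotated <- c(ref[5:12], ref[1:4])
  expect_true(arrangement_compare(rotated)$matches_reference_order)
  expect_true(arrangement_compare(rev(ref))$matches_reference_order)

  scrambled <- c("VIRB1", "VIRB9", "VIRB2", "VIRB3", "VIRB3")
  out <- arrangement_compare(scrambled)
  expect_equal(out$duplicated, "VIRB3")
  expect_false(out$matches_reference_order)
  expect_equal(out$matches_reference_order,
               oracle_subseq_rotations(out$observed_order, ref))
  # oracle agreement on random arrangements
  set.seed(51)
  for (i in 1:50) {
    obs <- sample(ref, sample(1:12, 1))
    got <- arrangement_compare(obs)
    expect_equal(got$matches_reference_order,
                 oracle_subseq_rotations(obs[!duplicated(obs)], ref))
  }
})

test_that("the classifier recovers planted truth without noise", {
  fix <- fixture_community()
  m <- classify_against_truth(fix$com)
  expect_equal(mean(m$klass == m$true_class), 1.0)
})

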