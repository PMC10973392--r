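make_db <- function(seqs, ids = sprintf("R%02d", seq_along(seqs))) {
  data.frame(taxon_id = ids, phylum = "P", class = "C", order = "O",
             family = "F", genus = "G",
             species = paste0("S_", ids), ssu_sequence = seqs)
}

test_that("reference curation filters by length and clusters greedily", {
  set.seed(40)
  db <- make_db(c(random_seq(1400), random_seq(1500)))
  out <- curate_reference_db(db)
  expect_equal(nchar(out$ssu_sequence), 1500L) # <=1400 removed
  a <- random_seq(1500)
  db3 <- make_db(c(a, a, mutate_to_identity(a, 90, seed = 1)))
  expect_equal(nrow(curate_reference_db(db3)), 2L)
  expect_warning(curate_reference_db(make_db(random_seq(1000))), "length")
})

test_that("curation matches the all-pairs greedy oracle with planted pairs", {
  set.seed(41)
  seqs <- character(12)
  for (i in 1:8) seqs[i] <- random_seq(sample(1450:1550, 1))
  # planted near-duplicates at 98% of earlier records
  for (i in 9:12) {
    seqs[i] <- mutate_to_identity(seqs[i - 8], 98, seed = i)
  }
  db <- make_db(seqs)
  expect_identical(curate_reference_db(db)$taxon_id,
                   oracle_curate(db)$taxon_id)
})

test_that("no two curated representatives reach the clustering identity", {
  set.seed(42)
  seqs <- c(vapply(1:5, function(i) random_seq(1500), character(1)))
  seqs <- c(seqs, mutate_to_identity(seqs[1], 98.5, seed = 9))
  out <- curate_reference_db(make_db(seqs))
  pairs <- combn(nrow(out), 2)
  ids <- apply(pairs, 2, function(p) {
    pairwise_identity(out$ssu_sequence[p[1]], out$ssu_sequence[p[2]])$identity
  })
  expect_true(all(ids < 97))
})

test_that("rank tiers are lower-inclusive and cover the identity range", {
  r <- assign_rank(c(98.2, 100, 97, 96.99, 94.5, 87.4, 86.5, 82, 78, 77))
  expect_equal(r$novelty_flag,
               c("known_species", "known_species", "known_species",
                 "novel_species", "novel_species", "novel_genus",
                 "novel_genus", "novel_family", "novel_order",
                 "novel_class"))
  expect_equal(r$resolved_rank[6], "family")
  expect_error(assign_rank(0), "identity")
  expect_error(assign_rank(101), "identity")
})

test_that("top-hit search applies the coverage filter and tie rules", {
  set.seed(43)
  db <- make_db(vapply(1:4, function(i) random_seq(1500), character(1)))
  gene <- list(sequence = db$ssu_sequence[3])
  hit <- search_top_hit(gene, db)
  expect_equal(hit$ref_id, "R03")
  expect_equal(hit$identity, 100)
  # a reference fragment covering 94% of the gene is dropped
  frag_db <- make_db(substr(db$ssu_sequence[3], 1, 1410), ids = "F1")
  expect_null(search_top_hit(gene, frag_db, min_coverage = 95))
  expect_error(search_top_hit(list(sequence = random_seq(1200)), db),
               "1400")
})

test_that("planted-identity genes recover their targets through search", {
  set.seed(44)
  db <- fixture_db()
  targets <- c(99, 97, 92, 85)
  for (tgt in targets) {
    g <- mutate_to_identity(db$ssu_sequence[2], tgt, seed = round(tgt))
    hit <- search_top_hit(list(sequence = g), db)
    expect_equal(hit$ref_id, db$taxon_id[2])
    expect_lt(abs(hit$identity - tgt), 0.5)
  }
})

profile_fixture <- function() {
  data.frame(
    gene_id = sprintf("g%d", 1:6),
    contig_id = c("c1", "c2", "c3", "c3", "c3", "c4"),
    contig_depth = c(10, 30, 8, 8, 8, 4),
    identity = c(99, 98, 100, 99.5, 97.2, 90),
    species = c("X", "Y", "Z", "Z", "Z", "W"))
}

test_that("profile abundances follow contig depths", {
  p <- profile_community(profile_fixture()[1:2, ])
  expect_equal(p$relative_abundance[p$taxon == "Y"], 75)
  expect_equal(p$relative_abundance[p$taxon == "X"], 25)
})

test_that("per-contig weighting counts a contig once per taxon", {
  x <- profile_fixture()
  p <- profile_community(x)
  z <- p[p$taxon == "Z", ]
  expect_equal(z$n_genes, 3L)
  expect_equal(z$n_contigs, 1L)
  expect_equal(z$relative_abundance, 100 * 8 / (10 + 30 + 8))
  pg <- profile_community(x, weighting = "per_gene")
  expect_equal(pg$relative_abundance[pg$taxon == "Z"],
               100 * 24 / (10 + 30 + 24))
  # identity < 97 is excluded from the species-level profile
  expect_false("W" %in% p$taxon)
})

test_that("profiles sum to 100, are scale invariant and match a summation oracle", {
  set.seed(45)
  n <- 30
  x <- data.frame(
    gene_id = sprintf("g%d", 1:n),
    contig_id = sprintf("c%d", sample(1:12, n, replace = TRUE)),
    identity = runif(n, 97, 100),
    species = sample(LETTERS[1:5], n, replace = TRUE))
  depth_tab <- setNames(runif(12, 1, 60), sprintf("c%d", 1:12))
  x$contig_depth <- depth_tab[x$contig_id]
  for (w in c("per_contig", "per_gene")) {
    p <- profile_community(x, weighting = w)
    expect_equal(sum(p$relative_abundance), 100, tolerance = 1e-6)
    # independent summation oracle
    want <- sapply(unique(x$species), function(sp) {
      rows <- x[x$species == sp, ]
      if (w == "per_contig") sum(depth_tab[unique(rows$contig_id)])
      else sum(rows$contig_depth)
    })
    want <- 100 * want / sum(want)
    expect_equal(setNames(p$relative_abundance, p$taxon)[names(want)],
                 want)
    # scale invariance
    x2 <- x
    x2$contig_depth <- x2$contig_depth * 7.3
    expect_equal(profile_community(x2, weighting = w)$relative_abundance,
                 p$relative_abundance)
  }
})

test_that("profile comparison reports shared abundant taxa", {
  a <- data.frame(taxon = c("X", "Q"), relative_abundance = c(10, 90))
  b <- data.frame(taxon = c("X", "Y"), relative_abundance = c(2, 0.5))
  cmp <- compare_profiles(a, b)
  expect_equal(cmp$above_threshold, "X")
  expect_equal(cmp$n_shared, 1L)
  expect_equal(cmp$combined_in_a, 10)
  expect_equal(cmp$combined_in_b, 2)
  same <- compare_profiles(a, a)
  expect_equal(same$n_shared, same$n_above_threshold)
  expect_equal(same$combined_in_a, same$combined_in_b)
  disjoint <- compare_profiles(
    data.frame(taxon = "M", relative_abundance = 100), b)
  expect_equal(disjoint$n_shared, 0L)
  expect_equal(disjoint$combined_in_a, 0)
})

test_that("16S genes are extracted with depth and length eligibility", {
  fix <- fixture_community()
  com <- fix$com
  genes <- extract_ssu_genes(com$contigs, com$annotations, com$depths)
  expect_true(all(genes$length >= 1400))
  d <- com$depths$mean_depth[match(genes$contig_id, com$depths$contig_id)]
  expect_true(all(d >= 5))
  # extracted sequences align to their source taxon at the planted level
  truth <- com$truth
  g1 <- genes[1, ]
  src <- truth$source_taxon[truth$contig_id == g1$contig_id]
  db <- fixture_db()
  id <- pairwise_identity(g1$sequence,
                          db$ssu_sequence[db$taxon_id == src])$identity
  targets <- as.numeric(strsplit(
    truth$ssu_targets[truth$contig_id == g1$contig_id], ",")[[1]])
  expect_true(min(abs(id - targets)) < 0.5)
})
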