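test_that("a single-taxon database has a valid full-length record", {
  db <- generate_reference_db(1, seed = 1)
  expect_equal(nrow(db), 1L)
  expect_gte(nchar(db$ssu_sequence), 1400)
  lineage <- db[, c("phylum", "class", "order", "family", "genus", "species")]
  expect_true(all(nchar(unlist(lineage)) > 0))
  expect_true(grepl("^[ACGT]+$", db$ssu_sequence))
  expect_error(generate_reference_db(0), "positive")
})

test_that("database generation is deterministic under a fixed seed", {
  expect_identical(generate_reference_db(4, seed = 5),
                   generate_reference_db(4, seed = 5))
})

test_that("lineages form a consistent hierarchy", {
  db <- generate_reference_db(24, seed = 2)
  for (pair in list(c("genus", "family"), c("family", "order"),
                    c("order", "class"), c("class", "phylum"))) {
    child <- db[[pair[1]]]
    parent <- db[[pair[2]]]
    expect_true(all(tapply(parent, child,
                           function(v) length(unique(v))) == 1L),
                info = paste("one", pair[2], "per", pair[1]))
  }
})

test_that("distinct species stay below the species identity threshold", {
  db <- generate_reference_db(8, seed = 7)
  pairs <- combn(nrow(db), 2)
  ids <- apply(pairs, 2, function(p) {
    pairwise_identity(db$ssu_sequence[p[1]], db$ssu_sequence[p[2]])$identity
  })
  expect_true(all(ids < 97))
})

test_that("mutate_to_identity applies the exact substitution count", {
  set.seed(10)
  s <- random_seq(1500)
  expect_identical(mutate_to_identity(s, 100, seed = 1), s)
  m <- mutate_to_identity(s, 97, seed = 1)
  expect_equal(nchar(m), 1500L)
  diff <- sum(strsplit(s, "")[[1]] != strsplit(m, "")[[1]])
  expect_equal(diff, 45L) # round((100 - 97)/100 * 1500)
  expect_equal(100 * (1500 - diff) / 1500, 97)
  expect_error(mutate_to_identity("", 90), "non-empty")
  expect_error(mutate_to_identity(s, 70), "70")
})

test_that("realized divergence matches the target by the alignment oracle", {
  set.seed(11)
  s <- random_seq(1500)
  m <- mutate_to_identity(s, 86.5, seed = 3)
  id <- pairwise_identity(m, s)$identity
  expect_gte(id, 86.0)
  expect_lte(id, 87.0)
})

test_that("fully circular communities duplicate the terminal overlap", {
  db <- fixture_db()
  cfg <- community_config(
    n_contigs = 6, n_ssu_contigs = 0, circular_fraction = 1,
    terminal_overlap_len = 2000,
    replicon_mix = c(chromosome = 0, megaplasmid = 0, repABC_plasmid = 0.4,
                     putative_plasmid = 0.3, bacteriophage = 0.2,
                     unclassified = 0.1),
    size_ranges = small_size_ranges(), seed = 4)
  com <- generate_community(cfg, db)
  for (s in com$contigs) {
    expect_identical(substr(s, 1, 2000),
                     substr(s, nchar(s) - 1999, nchar(s)))
  }
  expect_true(all(com$truth$true_circular))
})

test_that("a pure repABC mix plants repC on every contig", {
  db <- fixture_db()
  cfg <- community_config(
    n_contigs = 8, n_ssu_contigs = 0,
    replicon_mix = c(chromosome = 0, megaplasmid = 0, repABC_plasmid = 1,
                     putative_plasmid = 0, bacteriophage = 0,
                     unclassified = 0),
    size_ranges = small_size_ranges(), seed = 5)
  com <- generate_community(cfg, db)
  expect_true(all(com$truth$true_class == "repABC_plasmid"))
  has_repc <- tapply(com$annotations$label, com$annotations$contig_id,
                     function(l) "REPC" %in% l)
  expect_true(all(has_repc[com$truth$contig_id]))
})

test_that("community generation is deterministic and truth rows are complete", {
  fix <- fixture_community()
  com <- fix$com
  com2 <- generate_community(fix$cfg, fixture_db())
  expect_identical(com, com2)
  expect_equal(nrow(com$truth), length(com$contigs))
  expect_identical(com$truth$contig_id, names(com$contigs))
  # planted 16S copy counts match emitted annotation rows
  ssu_rows <- table(com$annotations$contig_id[
    com$annotations$label == "SSU_RRNA"])
  for (i in seq_len(nrow(com$truth))) {
    id <- com$truth$contig_id[i]
    n <- if (id %in% names(ssu_rows)) unname(ssu_rows[id]) else 0L
    expect_equal(com$truth$n_ssu[i], as.integer(n))
  }
  expect_error(generate_community(fix$cfg, fixture_db()[0, ]), "non-empty")
})
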