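# Shared fixtures, built once per test run.

small_size_ranges <- function() {
  list(chromosome = c(1e6, 1.15e6),
       megaplasmid = c(1e6, 1.1e6),
       repABC_plasmid = c(8e3, 4e4),
       putative_plasmid = c(8e3, 4e4),
       bacteriophage = c(1e4, 3e4),
       unclassified = c(1e4, 3e4),
       ssu_fragment = c(3e4, 6e4))
}

.fixture_env <- new.env(parent = emptyenv())

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

fixture_db <- function() {
  cached_fixture("db", function() generate_reference_db(6, seed = 11))
}

# A mid-sized noise-free community reused by classifier and pipeline tests.
fixture_community <- function() {
  cached_fixture("community", function() {
    cfg <- community_config(
      n_contigs = 30L, n_ssu_contigs = 6L,
      size_ranges = small_size_ranges(),
      depth_lognormal = c(mu = 3, sigma = 0.6),
      seed = 7L)
    list(cfg = cfg, com = generate_community(cfg, fixture_db()))
  })
}

fixture_demo <- function() {
  cached_fixture("demo", function() {
    dir <- file.path(tempdir(), "phyllotig-demo-fixture")
    suppressMessages(make_demo(420, dir))
  })
}

classify_against_truth <- function(com, annotations = NULL) {
  ann <- if (is.null(annotations)) com$annotations else annotations
  contig_df <- data.frame(contig_id = names(com$contigs),
                          length = nchar(com$contigs),
                          circular = com$truth$true_circular)
  fv <- build_feature_table(ann, contig_df, com$external_scores)
  calls <- classify_replicons(fv)
  merge(calls, com$truth[, c("contig_id", "true_class")], by = "contig_id")
}
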