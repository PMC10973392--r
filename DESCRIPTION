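Package: phyllotig
Title: Post-Assembly Analysis of Long-Read Phyllosphere Metagenomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the contig-level analysis of long-read metagenome
    assemblies from plant-associated microbial communities. Implements
    depth-based high-quality contig filtering and assembly summary
    statistics, detection of circular contigs by terminal sequence
    overlap, curation of a full-length 16S rRNA reference set with
    tiered identity-based taxonomy (species through class) and
    depth-weighted community profiling, and rule-based classification of
    contigs into chromosomes, megaplasmids, repABC plasmids, putative
    plasmids, bacteriophages and unclassified elements, including
    VirB/VirD4 type-IV secretion system completeness and arrangement
    scoring. A ground-truthed synthetic community generator makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
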