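Package: paradiverge
Title: Epigenome Divergence Between Paralogous Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies divergence of DNA methylation and chromatin state
    between the two copies of segmentally duplicated regions within a single
    sample. Builds base-level coordinate maps from pairwise duplication
    alignments, enumerates paralogous CpG site pairs, calls methylation
    discordance with Fisher's exact test against a region-shuffling
    permutation null, scores chromatin divergence in mappability-masked
    500-bp windows with binomial tests, detects lineage-specific Alu
    insertions from genome alignment chains and profiles methylation in
    their flanks across species, and fits an interaction model linking
    differentiation-associated methylation change to paralog divergence.
    Ships a synthetic-data generator with planted ground truth so the whole
    workflow is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    data.table,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
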