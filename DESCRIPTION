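Package: famexpress
Title: Cross-Species Gene-Family Comparative Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Builds ortholog gene families from filtered pairwise protein
    similarity evidence with Markov clustering, detects species-specific and
    high-copy families, aggregates time-course RNA-seq expression to the
    family level (summed FPKM), computes an uncertainty-penalized posterior
    log2 fold-change statistic with up/down/unchanged calls, clusters
    fold-change trajectories across species with k-means, transfers
    functional annotation to unannotated species-specific families by
    co-expression (Pearson correlation), cross-tabulates phase-matched
    expression trends between species, and performs hypergeometric GO-term
    enrichment. Includes a synthetic-data generator with planted ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    igraph,
    jsonlite,
    yaml,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
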