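Package: g4tier
Title: Evidence-Tiered Analysis of G-Quadruplex Sites in Genomic Context
Version: 0.1.0
Authors@R:
    person("g4tier", "developers", email = "g4tier@example.org", role = c("aut", "cre"))
Description: Integrative analysis of G-quadruplex (G4) sites combining
    sequence-based prediction with ChIP-seq evidence. Predicts G4 sites by
    a run-length guanine scoring scheme, partitions candidate sites into
    evidence tiers (ChIP-only, ChIP plus predicted, predicted-only),
    quantifies their genomic distribution and density, relates them to gene
    expression, epigenomic tracks and CpG methylation, fits and applies an
    eight-feature elastic-net logistic model of high versus low expression,
    and tests 6-mer enrichment in G4 flanking sequences ("feet") with a
    binomial null and Bonferroni correction. Ships a seeded synthetic-data
    generator that emulates every input with ground-truth bookkeeping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    BiocGenerics,
    Biostrings,
    rtracklayer,
    glmnet,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
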