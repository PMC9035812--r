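Package: migseqr
Title: Evaluation Toolkit for MIG-Seq Genotyping Pipelines
Version: 0.1.0
Authors@R: person("migseqr", "maintainers", email = "migseqr@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate reduced-representation genotyping by MIG-seq
    (multiplexed inter-simple-sequence-repeat genotyping by sequencing):
    scanning genomes for the targeted microsatellite motif classes, computing
    mapped-base-count coverage statistics from per-base depth tables,
    quality-controlling genotype matrices, estimating all-pairs nucleotide
    diversity with marker-count extrapolation, measuring heterozygous-call
    error against coverage depth with a virtual-F1 construction, and two-point
    linkage / single-marker QTL summaries. A synthetic-data generator with
    known truth tables (SSR-bearing genomes, diverged accession panels, F2 and
    recombinant-inbred crosses, overdispersed locus coverage) supports
    end-to-end testing without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    methods,
    stats,
    tools,
    utils,
    withr,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    SummarizedExperiment,
    VariantAnnotation,
    optparse
Suggests:
    testthat (>= 3.0.0),
    rtracklayer
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
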