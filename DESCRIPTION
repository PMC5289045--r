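Package: plastmarker
Title: Species-Diagnostic SNP Discovery and Gel-Based Marker Design for
    Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Plastmarker", "Developers", email = "plastmarker@example.org",
           role = c("aut", "cre"))
Description: A pipeline for discovering fixed interspecific single nucleotide
    polymorphisms among closely related chloroplast genomes from pooled
    multi-genotype short-read sequencing, and for converting those SNPs into
    gel-scorable CAPS (cleaved amplified polymorphic sequence) and
    tetra-primer ARMS-PCR assays. Includes structural characterization of
    plastomes (inverted-repeat detection, quadripartite LSC/SSC/IR
    partition, GC content, gene-order inversion blocks), pairwise
    coding-region divergence ranking, sliding-window identity profiles,
    in-silico PCR and restriction digestion with gel band-pattern
    prediction, and a synthetic-data generator that emulates pooled
    plastome sequencing of contrasting outcrossing and apomictic species
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    optparse,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation
Config/testthat/edition: 3
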