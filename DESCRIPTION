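Package: a3gclust
Title: Detection of APOBEC3G-Induced Germline Mutation Clusters in
    Comparative Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for detecting the footprint of APOBEC3G (A3G)
    cytidine-deaminase activity in germline evolution from multi-species
    alignments. Lineage-specific substitutions are called by
    outgroup-confirmed parsimony, chained into clusters of nearby
    mutations, classified by their shared ancestral nucleotide, and
    scored with a negative-binomial cluster P-value. Clustered mutations
    are then tested for enrichment of deaminase sequence motifs (CC/CCC
    for A3G and related APOBEC/AID motifs) against genomic, randomized
    and local-context backgrounds, with CpG-deamination controls, a full
    48-trinucleotide scan, functional-region fold-change analyses and
    block-bootstrap standard errors. A synthetic four-taxon alignment
    generator with planted deaminase cluster events makes every stage of
    the pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
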