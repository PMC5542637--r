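Package: lamis
Title: Integration-Site Analysis for LAM-PCR Vector Safety Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A verifiable pipeline for adeno-associated viral (AAV) vector
    integration-site (IS) analysis from linear amplification-mediated PCR
    (LAM-PCR) sequencing reads. Simulates ground-truthed LAM-PCR amplicons
    from planted integration events and concatemeric episomes (restriction
    digest truncation, linker ligation, substitution errors), classifies
    reads into vector-genome (IS), vector-vector (concatemer), internal and
    unclassified junctions, maps genomic fragments with a k-mer
    seed-and-extend aligner resolving unique versus multi-locus placements,
    collapses junctions into integration sites with semiquantitative clonal
    abundances, and tests for chromosomal hotspots and cancer-gene
    enrichment against synthetic random datasets using Fisher's exact
    statistics with multiple-testing control.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
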