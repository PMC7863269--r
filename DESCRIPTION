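Package: plastidscan
Title: Comparative Analysis of Chloroplast Genomes: Structure, Microsatellites,
    Indels, Diversity Hotspots and Distance Phylogenetics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative plastome analysis. Delimits the
    quadripartite structure (LSC, SSC and the inverted repeat pair) of
    circular chloroplast genomes, scans for perfect microsatellites (SSRs)
    with per-motif-length repeat thresholds, calls and classifies indel
    events (replication-slippage versus other) from whole-genome multiple
    alignments, computes site classification and sliding-window nucleotide
    diversity to rank mutation hotspots against universal DNA barcodes, and
    builds distance-based phylogenies from sequence and binary indel
    characters. A seeded simulator generates annotated quadripartite
    genomes evolved along a known tree, with ground-truth alignments, indel
    events and SSR catalogues, so every analysis stage can be validated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    BiocGenerics,
    GenomicRanges,
    ape
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, Phylogenetics, SequenceMatching, Alignment,
    ComparativeGenomics
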