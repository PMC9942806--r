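Package: macsome
Title: Somatic Genome Architecture and Domesticated-Transposase Analyses
    for Ciliate Macronuclear Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the architecture of extensively fragmented
    ciliate somatic (macronuclear) genomes from long sequencing reads:
    detection of telomeric repeat runs on reads, calling of alternative
    telomere addition sites (ATASs) from read-to-assembly alignments,
    estimation of the mean inter-telomere distance (DNA molecule length)
    and related genome statistics, catalytic-triad and cysteine-rich-domain
    annotation of PiggyBac transposase homologs, pairwise dN/dS screening
    (Nei-Gojobori style) under alternative genetic codes, and developmental
    fold-change ranking of gene expression.  Ships seeded simulators for
    telomere-capped minichromosome genomes, HiFi-like reads, codon-sequence
    pairs evolved at a chosen dN/dS, and count matrices with planted
    up-regulation, so every stage of the pipeline is testable with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble
Suggests:
    BiocGenerics,
    Rsamtools,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
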