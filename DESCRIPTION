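Package: mixasm
Title: Multi-k De Bruijn Transcriptome Assembly, Read Simulation and
    Assembly Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for de novo transcriptome assembly with
    multiple k-mer sizes. Simulates paired-end transcriptome shotgun reads
    with power-law expression levels and a position-ramped substitution
    error profile; assembles reads with a built-in de Bruijn (Euler-path)
    assembler over a schedule of k values; merges the per-k contig sets by
    exact suffix-prefix overlaps or a second de Bruijn pass; remaps reads to
    the merged contigs for expression counts; and scores assemblies against
    reference transcripts with overlap and consistent precision/recall,
    contig statistics (N50), transcripts-detected, and the Lander-Waterman
    expected-contig model of the optimum k.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
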