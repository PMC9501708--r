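Package: orthodiv
Title: Relative Divergence of Orthologous Coding Sequences
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares how far two lineages have diverged from a common
    reference species over sets of orthologous coding sequences (CDSs).
    Implements local pairwise alignment with affine gap penalties
    (Gotoh dynamic programming, BLAST-like scoring), a gap-aware
    similarity statistic and its relative-divergence difference between
    lineages, alignment-length filtering, threshold categorisation with
    summary counts, nucleotide and amino-acid p-distances with pairwise
    deletion, and a branch-specific sequence-evolution simulator used to
    generate ortholog triplets for fully offline, reproducible analyses.
    The motivating application is the comparison of rabbit-human versus
    mouse-human divergence across innate-immunity genes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
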