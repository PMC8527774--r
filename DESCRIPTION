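Package: divscan
Title: Substitution Hotspot Scans and McDonald-Kreitman Tests for
    Pairwise Sequence Divergence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects non-uniform clustering of interspecies substitutions
    along a pairwise sequence alignment using a cumulative deviation
    statistic (G) with significance assigned by Monte Carlo resampling of
    event positions without replacement, and contrasts within-species
    polymorphism against between-species divergence with McDonald-Kreitman
    style contingency tests for coding and noncoding regions.  Substitution
    and indel events are extracted from aligned FASTA with an explicit
    alignment-column coordinate system and optional mapping to promoter
    (TSS-anchored) coordinates.  A synthetic-data generator produces null
    and hotspot-bearing pairwise alignments and ingroup/outgroup codon
    panels with controlled polymorphism and divergence composition, so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
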