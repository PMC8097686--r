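Package: tandemscan
Title: Detection of Long Tandem Repeats in Individual Noisy Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects long (over 1000 nt) tandem repeats directly in single
    noisy long reads (10-20 percent error) without a reference genome.
    Candidate repeat intervals are located by scanning k-mer frequency
    vectors of sliding windows with a boundary peak statistic over a
    geometric grid of (k, window) patterns; the consensus repeat unit is
    reconstructed by greedy heaviest-cycle traversal of a de Bruijn graph,
    repaired by k-mer frequency transition analysis and by Bonferroni-
    corrected multiple-alignment column tests, and scored against the read
    with wraparound dynamic programming.  Overlapping calls are resolved by
    pseudo-disjoint weighted chaining with optimal split points.  Includes
    a seeded synthetic-read benchmark generator with substitution/
    insertion/deletion error channels and an evaluation harness
    (rotation-aware unit identity, repeat-length error, sensitivity).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    dplyr,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
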