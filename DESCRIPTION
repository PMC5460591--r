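Package: wdcj
Title: Genome Rearrangement by Double Cut and Join with Intergene Sizes
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models genomes as weighted perfect matchings in which each edge
    is a gene adjacency carrying its intergene size (nucleotides), and
    implements the weighted double cut and join (wDCJ) rearrangement
    operation, which redistributes the intergene nucleotides of the two
    replaced adjacencies while conserving their sum. Provides breakpoint
    graph construction with per-cycle imbalances, the exact wDCJ distance
    n - c + 2m via a fixed-parameter 3^n_u dynamic program and via an
    integer-programming formulation solved by branch and bound, a
    4/3-approximation, explicit optimal sorting scenarios (merges before
    splits), hard-instance generation by reduction from 3-Partition, and a
    Markov chain simulator of evolution by wDCJ with equilibrium sampling
    and symmetric Dirichlet maximum-likelihood fitting of the stationary
    intergene size distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
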