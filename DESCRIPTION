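Package: bpmedian
Title: Breakpoint Medians of Circular Genomes via the Traveling Salesman Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for studying the breakpoint median problem on circular
    unichromosomal genomes, unsigned and signed. Provides circular genome
    representations canonicalized up to rotation and reflection, adjacency
    sets and breakpoint distances, exact k-median solving through a
    reduction to the Traveling Salesman Problem (branch and bound with
    Held-Karp lower bounds, plus brute-force and dynamic-programming
    oracles), seed-varied sampling of alternative optimal medians, swap
    randomization of gene orders, and simulation drivers that track how
    median solutions drift towards the input genomes ("corners") while a
    shrinking minority remain at compromise positions in the middle.
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
    ggplot2,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
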