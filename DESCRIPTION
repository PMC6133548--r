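Package: bundleorder
Title: Quantifying Dendrite Order in Nerve Bundles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-automated quantification of the ordered arrangement of three
    labeled dendrites within a nerve bundle. Extracts 3D dendrite traces from
    multi-channel fluorescence image stacks with a brightest-path (Dijkstra)
    search, converts trace triplets into contiguous cross-sections with
    pairwise distances and middle-dendrite calls, classifies bundles as
    fasciculated or defasciculated against an age-matched reference by a
    run-length z-score rule, and tests population-level order with chi-squared
    and Fisher 3x2 permutation-rank statistics. Includes a synthetic phantom
    generator producing ground-truth-annotated image stacks and categorical
    populations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
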