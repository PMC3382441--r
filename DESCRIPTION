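Package: dlrecon
Title: Rooting and Error Correction of Unrooted Gene Trees Under the
    Duplication-Loss Cost
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reconciles unrooted gene trees with a rooted species tree under
    the weighted gene duplication-loss (mutation) cost. Finds all optimal
    rooting edges in linear time via a directed edge labeling of the gene
    tree, maintains the optimal-edge set and optimal cost in constant time
    across nearest-neighbor-interchange (NNI) rearrangements, and searches
    the k-NNI neighborhood of a gene tree (optionally restricted to weak,
    i.e. short, edges) for the error-corrected topology and rooting of
    minimum cost. Includes a hill-climbing heuristic for the error-corrected
    gene-duplication supertree problem and a birth-death gene-family
    simulator with branch lengths and NNI error injection for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
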