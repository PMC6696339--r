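Package: fragdiv
Title: Structural Diversity Metrics and Diverse Selection for Fragment
    Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Quantitative design of fragment screening libraries for
    fragment-based drug discovery. Reads and canonicalizes SMILES
    collections, applies an adapted Rule-of-3 physicochemical filter
    together with reactive-group and fluorine-count filters, generates
    radial (extended-connectivity) fingerprints hashed to 64-bit feature
    identifiers, selects diverse sub-libraries by directed sphere
    exclusion with Tanimoto distance (random selection as control), and
    scores libraries with three diversity metrics: mean nearest-neighbor
    Tanimoto similarity, fingerprint richness, and true diversity (the
    exponential of Shannon entropy over feature abundances). Cubic-spline
    size-diversity curves estimate the minimum library size achieving a
    diversity threshold. A seeded generator of redundant fragment-like
    catalogues (analog families plus singletons) supports fully offline
    benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineOB,
    ChemmineR,
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
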