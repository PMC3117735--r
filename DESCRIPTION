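Package: leafdist
Title: Edit Distances, Consensus and Frequent Subsplits for Leaf-Labelled Trees on Free Leafsets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Distance measures and consensus methods for unrooted leaf-labelled
    trees whose leafsets may differ. Implements a parametrizable tree edit
    distance built from contraction and pruning operations with explicit
    forced-contraction accounting (a metric), its no-forced-contraction
    variant, Robinson-Foulds and maximum-agreement-subtree reference
    distances, strict/majority/tree-edit consensus, frequent-subsplit mining
    with representative splitsets and a derived dissimilarity, and a seeded
    random-tree/mutation experiment harness for comparing the measures.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    stats,
    tibble,
    utils
Suggests:
    phangorn,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
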