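Package: wunifrac
Title: Weighted UniFrac Distances and Permutation Significance Tests with
    Compact and Expanded Tree Semantics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the weighted UniFrac distance between microbial
    communities on a rooted phylogeny and its label-permutation significance
    test, under the two permutation semantics that arise from the two
    interchangeable input formats: compact trees whose leaves carry sample
    labels with abundance counts, and expanded trees in which every
    individual is a unit-count leaf attached by a zero-length branch.
    Provides the invertible transform between the two forms, exact
    enumeration and Monte-Carlo null distributions, all-pairs distance
    matrices and significance tables, readers and writers for Newick trees
    and UniFrac-style environment files, a synthetic fixture generator, and
    a command-line interface. The two semantics can give very different
    p-values for semantically identical input; this package makes that
    discrepancy measurable and avoidable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
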