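Package: evoiso
Title: Species-Level Evolutionary Isolation Metrics for Conservation
    Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes eleven species-level evolutionary isolation scores on
    rooted (generally ultrametric) phylogenies: pendant edge, fair
    proportion / evolutionary distinctiveness, equal splits, the Shapley
    value of the spanning-length game, the Vane-Wright and May-Vane-Wright
    node counts, the Nixon-Wheeler unweighted and weighted indices, average
    pairwise distance, the Rao quadratic entropy maximising weights, and an
    expected character-rarity score.  Provides the machinery to compare
    them: birth-death tree simulation conditioned on tip number, score
    standardisation, inter-metric Euclidean distance matrices,
    average-linkage clustering with 50 percent majority-rule consensus,
    captured-variation subset selection, a uniqueness-versus-originality
    decomposition, clade-size scaling profiles, and EDGE-style ranked
    priority lists built from isolation scores and threat categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    stats,
    utils
Suggests:
    jsonlite,
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
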