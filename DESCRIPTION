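Package: dichroma
Title: Decomposing Sex-Specific Color Evolution and Dichromatism on
    Phylogenies
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct the evolutionary history of male and
    female coloration in CIELAB color space along a time-calibrated
    phylogeny, and to decompose changes in sexual dichromatism into male-
    and female-driven components. Implements a phylogenetic ridge
    regression that estimates ancestral color states at every node and a
    3-D rate vector on every branch, scalar projections of those rate
    vectors onto the dichromatism axis, rate-ratio and contribution-slope
    summaries, a sex-label permutation test, Pagel's lambda for
    dichromatism with a parametric bootstrap interval, image-based color
    centroid extraction, and a synthetic-data generator with known ground
    truth for Darwinian (male-driven) and Wallacean (female-driven)
    scenarios.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    farver,
    png,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
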