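Package: massembly
Title: Molecular Assembly Indices and Mass-Spectrometry Biosignature Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the molecular assembly index (MA) of small molecules
    with a split-branch upper-bound algorithm over bond-labelled molecular
    graphs, together with an exact brute-force oracle for small structures.
    Bounds the probability of unconstrained (chance) formation of a molecule
    as a function of its MA with a Monte-Carlo random-walk model on weighted
    trees. Estimates the MA of ions in complex mixtures from tandem
    mass-spectrometry (MS2) fragmentation peak counts via quantile-regression
    calibration, and classifies samples by their maximum estimated MA, the
    basis of an agnostic molecular biosignature assay.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    mzR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
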