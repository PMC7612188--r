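Package: axonmt
Title: Quantitative Analysis of Axonal Microtubule Architecture in Cryo-Electron Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the quantitative cryo-electron tomography
    analysis of axonal microtubules, exercised end-to-end on synthetic
    tomograms with known ground truth. Generates microtubule lattice scenes
    (11-15 protofilaments, polarity-dependent subunit slew, lattice breaks,
    tapered ends, luminal particles, missing-wedge corruption), reads and
    writes MRC volumes, filament point models and particle tables, extracts
    and aligns subtomograms, determines microtubule polarity by multivariate
    statistical analysis and multireference alignment classification, counts
    protofilaments and detects protofilament-number transitions, quantifies
    luminal particle density at lattice breaks and ends, and measures
    protofilament end morphology (deviation paths and taper lengths).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
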