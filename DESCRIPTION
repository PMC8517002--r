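Package: diasense
Title: Peptide-Centric Analysis of Data-Independent Acquisition
    Proteomics with Deep Chromatogram Representations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Peptide-centric scoring of data-independent acquisition (DIA)
    mass spectrometry runs against transition-list spectral libraries.
    Extracts representative spectral matrices (RSMs) of 170 ion
    chromatograms per candidate peak group, scores them with a recurrent
    neural representation model trained against in-silico decoys,
    calibrates library retention times with RANSAC or LOWESS, rescores
    candidates by positive-unlabeled learning with gradient-boosted trees,
    controls the false discovery rate by target-decoy competition, and
    quantifies precursors and proteins by correlation-weighted
    chromatogram areas.  Includes a synthetic DIA experiment generator
    for validation and two-species / pseudo-mass-shift benchmarking
    utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    mzR,
    xgboost,
    ranger,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
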