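Package: flimmix
Title: Fluorophore Unmixing from Fluorescence Lifetime Decays with
    Feed-Forward Neural Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Determines the fractional contributions of individual
    fluorophores to a mixed multi-exponential fluorescence decay recorded
    by time-correlated single-photon counting (TCSPC). Provides a
    photon-level Monte-Carlo simulator of TCSPC decay histograms with
    laser pulse shape, detector jitter and Poisson background; a small
    fully connected feed-forward neural-network regressor trained on
    simulated mixtures (with optional fine-tuning on labelled
    experimental curves); a fixed-lifetime non-negative least-squares
    baseline; accuracy and precision statistics for predicted fractions;
    and lifetime-spacing experiments that yield a minimal-spacing design
    law for fluorophore multiplexing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
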