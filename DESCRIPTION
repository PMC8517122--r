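Package: dilvr
Title: Damage-Informed Lung-Ventilator Waveform Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature-anchored modelling of mechanical-ventilator pressure and
    volume waveforms. Builds periodic breath signals from modular primitives
    (thresholded sinusoids, tanh squashing, first-order recursive tracking,
    leaky differencing, masked normalization), composes them into a
    damage-informed lung-ventilator (DILV) model with interpretable
    parameters for inspiratory/expiratory gradients, plateau-pressure peaks
    associated with ventilator dyssynchrony, the low-volume pressure knee,
    and PEEP. Provides breath-by-breath parameter estimation by multi-start
    bounded nonlinear least squares with uncertainty summaries, a linear
    single-compartment comparator model, a model-derived lung-compliance
    readout, synthetic breath and cohort generators with known ground truth,
    waveform file input/output, and breath segmentation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
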