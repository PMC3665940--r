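Package: cpgdrnn
Title: Central Pattern Generator Modelling with Dynamic Recurrent Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the spinal central pattern generator for human locomotion as
    a fully connected continuous-time recurrent neural network with adaptive
    per-unit time constants, trained by adjoint-equation gradients to transform
    three-harmonic sinusoidal oscillations into the six sagittal elevation-angle
    trajectories of the lower limbs (thigh, shank, foot, both sides) across
    walking speeds. Includes a synthetic gait generator with realistic spectral
    and planar-covariation structure, FFT harmonic feature extraction, sine-wave
    input construction, similarity-index and planar-covariation evaluation, and
    drivers for single-pattern and multi-velocity training experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
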