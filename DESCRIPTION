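Package: scatterfit
Title: Small-Angle Scattering and Quasielastic Models with Attribute-Aware
    Multi-Dataset Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Containers for matrix-like measurement data with named metadata
    attributes and lossless ASCII round trips, simultaneous chi-square fitting
    of many datasets with automatic binding of model parameters to dataset
    attributes, a library of small-angle scattering form factors and fluid and
    crystalline structure factors (including a screened-Coulomb rescaled mean
    spherical approximation solver that examines all roots of the closure
    quartic), orientation-averaged point-cloud scattering with Fibonacci-grid
    spherical averaging, quasielastic neutron scattering models in the time and
    frequency domains with a Fourier bridge, and instrument resolution smearing
    and iterative Lake desmearing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    pracma,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
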