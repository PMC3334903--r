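Package: pmkin
Title: Parameter Estimation and Comparison for Phenotype MicroArray Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing OmniLog Phenotype MicroArray (PM) respiration
    kinetics recorded on 96-well plates. Provides three estimators of the four
    canonical curve parameters (lag phase lambda, maximum slope mu, maximum
    height A, area under the curve): a re-implementation of the instrument's
    native parametric algorithm, nonlinear least-squares fits of four standard
    growth models with AIC-based selection, and a cubic smoothing-spline fit
    with tangent-based lag extraction. Includes nonparametric bootstrap
    confidence intervals, confidence-interval overlap comparisons with minimum
    expectable differences, simultaneous confidence intervals for user-defined
    differences of group means, archetypal analysis of curve shapes with
    elbow-based model-order selection, plate-level visualisation (trellis curve
    grids, level maps, CI dot plots), plate CSV input/output, and a synthetic
    plate generator emulating factorial PM experiment designs and the observed
    taxonomy of curve shapes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    lattice,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
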