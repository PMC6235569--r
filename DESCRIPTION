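Package: epiosc
Title: Shear-Induced Oscillation Analysis for Epithelial Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for the collective response of an epithelial
    monolayer to localized in-plane shear: construction, folding and binning
    of velocity kymographs from particle image velocimetry (PIV) output,
    numerical integration into displacement traces, wave-front propagation
    speed estimation, conversion of on-chip spring-sensor displacement to
    force with exponential relaxation fitting, damped-sinusoid fitting of
    collective velocity oscillations with nonparametric condition comparison,
    and simulation of a lumped spring-damper-inerter mechanical circuit that
    reproduces the damped oscillatory response. Includes a seeded synthetic
    data generator emulating the measurement structure of the sheared
    monolayer experiments, so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
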