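Package: splanchnirs
Title: Finite-Element Simulation of Abdominal NIRS for Infant Splanchnic Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuous-wave near-infrared light transport through a parametric
    model of the infant abdomen, solved with a first-order finite-element
    discretization of the photon diffusion equation under Robin (partial-flux)
    boundary conditions. Includes per-tissue optical property tables at 750 nm
    with Beer-Lambert blood absorption, modified Beer-Lambert layer-sensitivity
    analysis, a synthetic shot-noise measurement model with
    calibration-by-interpolation, and contrast-to-noise-ratio optimization of
    the source-detector distance for splanchnic (intestinal) oximetry sensor
    design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
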