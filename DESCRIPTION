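Package: cartdyn
Title: Dynamic Compression Modelling of Human Articular Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constitutive modelling and finite-element simulation of human
    articular cartilage under physiological dynamic compression. Implements
    linear elastic, Neo-Hookean and third-order Ogden material laws with a
    ramp plus 1 Hz sinusoidal pressure protocol, a nonlinear plane-stress
    finite-element solver with a homogeneous-deformation oracle, calibration
    of material constants from quasi-static stress-strain curves with
    Drucker stability screening, dynamic mechanical analysis (DMA) output
    metrics (ramp compression, dynamic amplitude, hysteresis), and a
    synthetic specimen-cohort generator for end-to-end validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    minpack.lm,
    yaml,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
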