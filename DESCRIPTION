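Package: umiflow
Title: Ultrasonic-Measurement-Integrated Blood Flow Simulation and Wave
    Intensity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples a two-dimensional incompressible Navier-Stokes solver on a
    staggered grid with color-Doppler velocity feedback (measurement-integrated
    simulation), a photoplethysmography/ECG pressure-measurement signal chain,
    and wave-intensity / PU-loop analysis of forward and backward arterial
    waves. Includes a synthetic twin-experiment generator (ground-truth
    pulsatile flow, Doppler frames, B-mode-like image stacks, Beer-Lambert
    photoplethysmography, synthetic ECG) so the whole pipeline can be validated
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    signal,
    EBImage,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    patchwork,
    generics,
    stats,
    utils,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
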