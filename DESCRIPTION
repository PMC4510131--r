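Package: virtuostat
Title: Continuous-Culture Control Engine and Virtual Bioreactor Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scriptable control engine for small-volume continuous culture
    (turbidostat and chemostat operation) together with a closed-loop virtual
    culture rig for testing control strategies entirely in software. Models
    optical growth monitoring at 560 nm by turbidity (Beer-Lambert) or by a
    phenol-red pH readout for cells too small to scatter light, Monod growth
    kinetics with substrate depletion and metabolic acidification, calibrated
    pinch-valve dilution fluidics with overflow protection, and four operating
    modes (batch monitoring, real-time feedback, threshold-activated, and
    time-interval dilution) over up to three independent channels. Includes
    offline analysis of experiment logs: calibration regressions, growth-rate
    estimation, generation accounting, and steady-state summaries.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
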