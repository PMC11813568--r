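Package: thermogate
Title: Simulation and Signal-Detection Analysis of Thermotactile Gating
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates yes/no cold-detection experiments in which concurrent
    touch reduces sensitivity to focal skin cooling, and analyses them with
    signal detection theory. Provides an equal-variance Gaussian observer
    model with tactile gating and auditory bias parameters, dual interleaved
    3-down/1-up weighted staircases with boundary carry-on for threshold
    estimation, generation of detection sessions with grid-location revisit
    constraints and matched-duration noise trials, loglinear-corrected
    sensitivity (d-prime) and response bias (C), and cohort-level planned
    comparisons including an a-priori sample-size calculation based on the
    noncentral t distribution.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
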