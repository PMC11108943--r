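Package: cuticond
Title: Cuticular-Conductance-Aware Analysis of Leaf Gas Exchange
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for correcting leaf gas-exchange measurements for cuticular
    conductance. Implements the conductance calculus partitioning leaf
    conductance to water into stomatal and cuticular components with their
    distinct water:CO2 diffusivity ratios (1.6 and 20), the ternary-corrected
    intercellular CO2 calculation, and a coupled Farquhar-von Caemmerer-Berry
    photosynthesis/diffusion solver used to quantify how ignoring cuticular
    conductance or instrument noise in conductance misestimates intercellular
    CO2 across leaf conductance and ambient CO2. Includes a synthetic
    infrared-gas-analyzer data generator (steady-state and constant-ramp CO2
    response protocols, empty-chamber drift, CO2-responsive stomatal dynamics,
    Gaussian conductance noise), empty-chamber calibration of constant-ramp
    (RACiR) curves, A/Ci curve fitting with corrected and uncorrected
    conductance pathways, and the red-light method for estimating cuticular
    conductance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    knitr
Config/testthat/edition: 3
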