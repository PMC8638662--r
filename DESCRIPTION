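Package: hypercal
Title: Cross-Nuclear Calibration and Kinetic Analysis for Hyperpolarized Carbon-13 MRI
Version: 0.1.0
Authors@R:
    person("Open", "Contributor", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for calibrating hyperpolarized 13C magnetic resonance
    experiments from the endogenous 23Na and 1H resonances. Implements
    cross-nuclear center-frequency and transmit-gain scaling, chemical-shift
    imaging (CSI) spectral processing with Lorentzian quantification, B0 and
    double-angle B1 field mapping, multichannel noise-correlation analysis,
    three 13C-pyruvate center-frequency predictors with Bland-Altman
    comparison, matching-pursuit spectral quantification, and two-site
    exchange (kPL) kinetic modelling of dynamic hyperpolarized spectra.
    Includes seeded synthetic-data generators for every pipeline stage and a
    command-line workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
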