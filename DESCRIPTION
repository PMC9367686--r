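Package: ra223sim
Title: Cellular Microdosimetry and Radiobiology of Radium-223 Exposures In Vitro
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte Carlo estimation of the mean alpha-particle absorbed dose to
    the nucleus of an attached cell from radium-223 decays uniformly
    distributed in culture medium, under a continuous-slowing-down
    approximation with an embedded stopping-power table for liquid water.
    Builds a treatment planner on the resulting dose factor and the 11.4-day
    decay law (required activity concentrations, stock volumes, dose rates),
    and provides the downstream radiobiological models used in alpha-particle
    cell experiments: linear-quadratic clonogenic survival fits with relative
    biological effectiveness at 50% survival, exponential-plateau DNA
    double-strand-break repair kinetics, and rule-based nuclear-morphology
    classification, together with synthetic-data generators that emulate the
    corresponding assays.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
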