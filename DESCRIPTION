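Package: cpuecal
Title: Calibrating Capture-Per-Unit-Effort Against a Fully Enumerated
    Snake Population
Version: 0.1.0
Authors@R:
    person("Field", "Ecologist", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to validate capture-per-unit-effort (CPUE) as an index
    of density for a closed, declining, fully enumerated snake population.
    Includes an individual-based simulator of an enclosed population
    sampled by nightly transect visual surveys and grid trapping, census
    enumeration by growth-rate back-extrapolation of each individual's
    presence to its inferred birth month, monthly effort-corrected CPUE
    construction, rarefaction of survey effort to reduced temporal schemes
    and spatial transect coverage, Poisson and negative binomial
    regression of abundance on CPUE with an area exposure offset, and
    residual-distance evaluation of prediction accuracy and precision
    including a hyperstability diagnostic.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
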