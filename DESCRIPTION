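Package: phytodisc
Title: Size-Structured Phytoplankton Growth and Ecosystem Modelling for
    Discrete, Distantly-Spaced Cells
Version: 0.1.0
Authors@R:
    person("phytodisc", "maintainers", email = "maintainers@phytodisc.org",
           role = c("aut", "cre"))
Description: Tools for modelling marine phytoplankton communities as
    populations of discrete, distantly-spaced cells. Provides closed-form
    arithmetic on power-law cell size spectra (total abundance, total
    occupied volume, mean diameters, nearest-neighbour spacing and
    boundary-layer overlap diagnostics), two-parameter production-resource
    curve forms for light- and nutrient-limited growth with deterministic
    least-squares fitting, a diffusion-based solver for nutrient-limited
    division rates of single cells (Sherwood/Peclet transport enhancement,
    carbon allometry, nitrogen quota iteration), and a steady-state
    size-structured phytoplankton-zooplankton ecosystem model with
    analytic fixed points, forward-Euler integration, diversity and
    size-distribution-slope diagnostics, and multispecies and mortality
    variants. Includes a JSON-configured command-line interface and a
    synthetic fixture generator for curve-fit recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
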