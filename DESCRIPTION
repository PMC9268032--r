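Package: monolayer
Title: Thermodynamic Analysis of Langmuir Monolayer Pressure-Area Isotherms
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of surface pressure-area (pi/A) isotherms of Langmuir
    monolayers at the air/water interface. Computes surface compressibility
    modulus profiles with Davies-Rideal phase-state classification, locates
    phase-transition and collapse points, quantifies compression-decompression
    hysteresis as enclosed loop area, and evaluates the thermodynamics of mixed
    (e.g. protein/lipid) films: additivity-rule area deviations and the Goodrich
    excess, ideal and total free energies of mixing as functions of surface
    pressure and composition. Includes a seeded synthetic isotherm generator
    based on an exponential two-dimensional equation of state with closed-form
    oracles for every derived quantity, a plain-text isotherm file format, and
    command-line entry points.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: graphics, jsonlite, pracma, stats
Suggests: optparse, testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
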