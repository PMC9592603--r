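Package: nanoexo
Title: Surface-Energy Prediction of Nanoparticle Exocytosis Rate Constants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts cellular exocytosis rate constants of coated
    nanoparticles from extended-DLVO (Lifshitz-van der Waals, electrostatic
    double-layer and Lewis acid-base) interaction energies computed from van
    Oss-Chaudhury-Good surface free-energy components. Builds
    distance-resolved energy profiles for nanoparticle-vesicle and
    vesicle-membrane pairs, extracts the exocytosis energy change, fits
    per-cell-line Arrhenius regressions ln(k_exo) = beta * dG + ln(A) with
    confidence intervals, decomposes frequency factors through a Boltzmann
    vesicle partition, and fits exocytosis time-series curves for the
    experimental rate constants. Includes readers and writers for
    nanoparticle property tables, a packaged interaction-energy fixture,
    seeded synthetic-data generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
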