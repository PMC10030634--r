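Package: beeheat
Title: Heat-Budget Modelling of Stationary Honeybee Foragers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mixed mechanistic/correlative heat-exchange models for stationary
    honeybee (Apis mellifera) foragers. Predicts metabolic energy turnover from
    body-part surface temperatures, ambient air temperature and global
    radiation; combines Stefan-Boltzmann radiative exchange, segment-wise
    convective heat transfer with air-temperature-dependent coefficients, and
    fixed evaporative loss, weighted by correlative coefficients fitted
    jointly to visit-level data by Levenberg-Marquardt least squares (with a
    closed-form linear-least-squares cross-check). Includes published coefficient presets,
    body-surface geometry from ellipsoid and sphere approximations, a seeded
    synthetic-visit generator for parameter-recovery studies, delimited-text
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    minpack.lm,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
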