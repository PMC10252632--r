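Package: drykin
Title: Thin-Layer Drying Kinetics, Moisture Diffusivity and Drying Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing convective (hot-air) drying experiments on
    plant material. Fits the ten classical thin-layer drying models (Newton,
    Page, Henderson-Pabis and its modified form, logarithmic, logistic,
    Midilli, Thompson, Verma, two-term) to moisture-ratio time series by
    multi-start nonlinear least squares, with the usual goodness-of-fit
    statistics (R2, root-mean-square deviation, reduced chi-square) and model
    ranking. Estimates effective moisture diffusivity from the truncated
    Fick-slab series, derives Arrhenius activation energy across drying
    temperatures, and computes the thermodynamic properties of the process
    (enthalpy, entropy, Gibbs free energy). Includes proximate-composition
    arithmetic (carbohydrate by difference, Atwater energy) and a seeded
    synthetic-data generator that emulates a gravimetric drying experiment
    with a progressive weighing schedule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    minpack.lm,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
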