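Package: silkcoat
Title: Transport and Postharvest Physiology of Silk Fibroin Edible Coatings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of silk-fibroin edible coatings and their effect on fruit
    postharvest physiology. Estimates effective membrane oxygen diffusivity
    from two-chamber permeation kinetics with rubber-stopper baseline
    correction, computes water vapour transmission rate and permeability from
    desiccant-cup weight series (ASTM E96 style), quantifies relative
    beta-sheet content from Amide III FTIR spectra by 12-Gaussian
    deconvolution, and derives respiration rate, dehydration and firmness
    metrics from headspace CO2, gravimetric and puncture-test records.
    Includes seeded synthetic-instrument generators for all five channels so
    every estimator is validated by parameter recovery against known ground
    truth, plus an end-to-end scenario pipeline with group-comparison
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    minpack.lm,
    stats,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
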