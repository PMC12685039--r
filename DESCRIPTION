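Package: warmflux
Title: Soil Nitrogen Gas Fluxes Under Experimental Warming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chamber-based soil nitric oxide (NO) and nitrous oxide
    (N2O) flux analysis in soil-warming experiments. Implements the hybrid
    accumulation + dynamic (vented chamber) flux estimator, water-filled pore
    space soil physics, exponential temperature-response (Q10) and quadratic
    moisture-response fitting with Q10-expected counterfactual fluxes,
    moisture-based upscaling of N2 emissions from N2O, net nitrogen
    mineralization and nitrification rates from laboratory incubations with
    Arrhenius extrapolation, and warming effect sizes (lnRR, RRn) including a
    cross-study regression of N2O warming responses on soil-moisture change.
    A seeded synthetic generator for soil climate, chamber closures, and
    incubations makes the entire chain testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    deSolve
Suggests:
    testthat (>= 3.0.0),
    minpack.lm,
    withr,
    optparse
Config/testthat/edition: 3
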