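Package: aeroscope
Title: Temperature-Induced Aerobic Scope Analysis from Intermittent-Flow
    Respirometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deriving a temperature-induced aerobic scope (TAS) from
    intermittent-flow respirometry of aquatic ectotherms. Raw closed-phase
    oxygen traces are turned into blank-corrected, mass-specific oxygen
    consumption rates with explicit quality gates; per-temperature rate
    profiles are fitted with a plateau-rise-collapse changepoint model to
    locate critical cold and warm temperatures, the temperature-induced
    standard and maximal metabolic rates (TSMR, TMMR), TAS, Q10 temperature
    coefficients, and a midpoint thermal optimum. A companion RT-qPCR stage
    implements relative quantification (RQ, normalization factors, NRQ,
    calibrated NRQ), geNorm reference-gene stability, log-scale confidence
    intervals, and exact Mann-Whitney comparisons. A seeded synthetic-data
    generator emulates the thermal-ramp study design so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
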