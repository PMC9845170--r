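Package: ebossflux
Title: Flying-Insect Biomass Density from Bistatic Optical Sensor Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis chain for entomological bistatic optical sensor
    (eBoss) recordings: reads raw photodetector voltage time series,
    detects insect transit events with a band-pass filter and an adaptive
    sliding threshold, classifies events by harmonic-series detection and
    estimates wingbeat frequency, converts events to body extinction cross
    sections under the flat-top beam approximation, calibrates and applies
    a power-law mass model (m = eta * sigma^(3/2)), and aggregates events
    into transit-time-weighted volumetric biomass density (mg/m^3) with
    daily, rolling and diel summaries. Includes a synthetic session
    generator with ground-truth ledgers so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
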