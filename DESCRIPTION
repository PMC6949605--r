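Package: sfxchip
Title: Background Budgets and Chip-Scan Analysis for Fixed-Target Serial
    Femtosecond Crystallography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning and analysing fixed-target serial femtosecond
    crystallography (SFX) experiments on pore-patterned silicon chips. Provides
    a Rayleigh-scattering photon-budget model for layered sample enclosures
    (graphene, PMMA, Mylar, water, gases), Poisson crystal-loading hit-rate
    statistics, a synthetic generator for 120 Hz chip-scan detector data, a
    per-shot background-analysis pipeline (single-photon gain calibration,
    pulse-energy-normalised radial profiles, median-intensity population
    classification, threshold hit finding), chip-coordinate heat maps and
    hit-rate fields, and a minimal CrystFEL stream reader for unit-cell
    statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
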