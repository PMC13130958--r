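Package: sedpflux
Title: Episodic Internal Phosphorus Loading from Sediment Resuspension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies episodic internal phosphorus loading from sediment
    resuspension in shallow lakes. Fits steady-state beryllium-7
    decay-biodiffusion profiles to sediment cores to estimate vertical mixing
    rates, mixing depths, inventories, depositional fluxes, particle residence
    times, settling rates and accumulation rates; tracks sequential-extraction
    phosphorus fractions (total and bioavailable pools); inverts pre/post-event
    changes in suspended particulate matter (SPM) to erosion depth and
    resuspended mass; retrieves SPM from single-band water-leaving reflectance;
    and scales thickness-weighted sediment phosphorus release to basin-wide
    totals on gridded SPM scene pairs. Includes seed-deterministic synthetic
    generators for cores, phosphorus profiles and resuspension events so every
    stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
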