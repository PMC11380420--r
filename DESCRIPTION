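Package: divetag
Title: Diel Vertical Migration, Activity and Thermal Niche Analysis for
    Archival Tag Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel archival tag (PSAT) records
    from fish: track cleaning and aggregation, solar/diel period
    classification, acceleration-burst ("fast start") detection,
    bias-corrected continuous Morlet wavelet analysis of depth series with
    AR(1) red-noise surrogate significance, daily diel-vertical-migration
    classification and between-individual clustering, weighted
    depth-temperature kernel density niche estimation with isopleths, and
    monthly depth-by-hour activity hotspot maps.  Includes a synthetic tag
    archive generator with known behavioural structure for validation, and
    an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
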