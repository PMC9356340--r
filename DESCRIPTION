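Package: accelharm
Title: Open-Source Accelerometry Measures and Activity-Count Harmonization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes minute-level open-source physical-activity measures
    (MIMS, ENMO, MAD, AI) from raw wrist-worn tri-axial accelerometry,
    applies raw-data quality control, count-based wear detection,
    valid-day selection, winsorization, and functional principal component
    analysis imputation of diurnal profiles, and fits penalized
    regression-spline harmonization mappings between ActiGraph activity
    counts and each measure, with cut-point translation and evaluation
    statistics (percentage errors of daily totals, cut-off classification
    metrics, smoothed 24-hour median curves). Includes seeded synthetic-data
    generators so the whole pipeline is testable without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    splines,
    signal,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mgcv,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
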