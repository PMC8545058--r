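Package: nightshift
Title: Epidemic-Induced Change and Recovery Analysis of Daily Nighttime-Light Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying changes in human activity from daily
    nighttime-light (NTL) radiance rasters during a large-scale epidemic.
    Implements quartile-fence (Tukey) outlier detection and repair of daily
    pixel time series, moonlight screening, development-corrected radiance
    change detection with decrease/background/increase classification,
    zone-level influence-intensity statistics graded by Jenks natural breaks,
    Anselin Local Moran's I cluster typing with conditional-permutation
    inference, lunar-calendar-matched recovery indices cross-validated
    against intra-city travel intensity, and fifth-order polynomial
    trajectory typing of daily radiance-deficit series. A seeded synthetic
    scene generator with planted ground truth makes every stage testable
    without satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    mgcv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
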