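Package: asvseasons
Title: Fourier-Based Seasonality Analysis of Amplicon Time Series from
    Moored Samplers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of amplicon (ASV) relative-abundance time series
    collected by autonomous moored samplers at two stations. Each ASV
    series is interpolated to daily resolution and decomposed by discrete
    Fourier transform; an annual seasonality score, phase and amplitude
    are extracted, ASVs are clustered by their Fourier features (k-means
    with BIC model selection), clusters are ordered and named by phase
    and annotated with polar day-length light classes, cross-station
    cluster overlaps are scored with a hypergeometric test, water-regime
    preference (meltwater vs mixed-layer year) is classified from log2
    yearly-abundance quotients, and year-to-year prosperity is compared
    by area-under-the-curve ratios. A synthetic two-station community
    generator with known seasonal, regime and membership ground truth
    supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
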