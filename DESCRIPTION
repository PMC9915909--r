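Package: ecolag
Title: Spatiotemporal-Lag Spatial Cross-Correlation of Ecological Quality
    and Life Expectancy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds a comprehensive ecological index (CEI) from five
    remote-sensing indicators (NDVI, LAI, GPP, LST, tasseled-cap wetness)
    by correlation-matrix principal component analysis with an
    80%-cumulative-variance selection rule, and relates it to regional
    life expectancy with an explicit temporal lag.  Provides Theil-Sen
    slope and Mann-Kendall trend tests, Getis-Ord Gi* cold/hot-spot
    z-scores, queen/rook contiguity and GAL spatial weights, and global
    and local bivariate Moran's I with a temporal offset, including
    permutation inference, Moran scatter values and LISA cluster labels.
    A synthetic-data module generates spatially autocorrelated indicator
    panels with a known lagged life-expectancy dependence so the whole
    pipeline can be exercised with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
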