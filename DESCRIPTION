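Package: gridrep
Title: Evaluating Regular Sampling Designs on Elevation-Like Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates regular sample arrangements (generic lattices with
    randomized offsets and the RAPELD 25 km2 trail-grid layout) over
    elevation-like raster surfaces, interpolates from the samples by inverse
    distance weighting, and scores representativeness (two-sample
    Kolmogorov-Smirnov), similarity (Pearson correlation) and accuracy (root
    mean square error) against the full surface. Trends of the metrics over
    sample size and surface heterogeneity are summarized with penalized-spline
    smooths, and break-points are detected with a permutation-based
    conditional-inference partitioner. A seeded Gaussian-random-field terrain
    generator emulates 5x5 km digital-elevation tiles at 90 m resolution so
    the whole pipeline runs from scratch at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    mgcv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
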