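Package: srrpower
Title: Simulation-Based Power Analysis for the Spatial Relative Risk Function
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the local statistical power of the spatial relative
    risk function, a kernel-based cluster detection statistic for two labelled
    point patterns (e.g. cancer cases and community controls). Point patterns
    are simulated under user-specified sampling models (multivariate normal
    clusters, complete spatial randomness, uniform discs) inside a polygonal
    study window; for each Monte-Carlo iteration the log relative risk surface
    is estimated by edge-corrected bivariate Gaussian kernel density
    estimation with an oversmoothing (maximal smoothing) bandwidth, tested
    knot-wise against the null of no clustering via its asymptotic normal
    distribution, and the per-knot rejection proportion is reported as local
    power together with the sufficiently powered region.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    parallel,
    jsonlite,
    yaml,
    rlang,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
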