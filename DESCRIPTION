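Package: mstconnect
Title: Minimum Spanning Tree Analysis of Wavelet-Based Functional Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for minimum-spanning-tree (MST) analysis of regional
    functional MRI time series. Computes maximal-overlap discrete wavelet
    transform (MODWT) correlation matrices per frequency scale, global
    bivariate connectivity measures with a mutual-information significance
    test, topological-overlap (TOM) edge re-weighting, Prim minimum spanning
    trees with global tree metrics, extreme-value-index (strong disorder)
    diagnostics, two-group topological comparison (superhighway extraction,
    betweenness gain/loss, geodesic tree clustering, survival ratio), rank
    and permutation statistics with covariate correction, and a synthetic
    two-group cohort generator with block-structured regional covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
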