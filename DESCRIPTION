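Package: thinedges
Title: Thin-Edge Extraction from Predicted Object Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing of predicted object-boundary images (ramp edges
    whose pixel intensity encodes per-pixel confidence) into one-pixel-wide,
    eight-connected thin edges.  Implements the Gray-Weighted Distance
    Transform (exact minimal accumulated-intensity cost of a four-connected
    path to the background), the Gray-Weighted Path Skeletonize that extracts
    the ridge of that cost surface as a thin edge, classic binary-thinning
    baselines, spur pruning with a diagonal-relative length limit, distance
    based and bounding-box based edge-quality metrics, and a discrete
    combinatorial search over the threshold / skeletonize / pruning
    parameters.  A synthetic generator renders known one-pixel curves as
    Gaussian-profile ramp boundaries with noise, irregularities and gaps so
    the whole pipeline can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    tiff,
    jsonlite,
    optparse,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
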