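Package: fimicdepth
Title: Robust Depth Estimation for Fourier Integral Light-Field Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Depth-map estimation for light fields captured with a Fourier
    integral microscope (FiMic), in which seven perspective views of the sample
    are recorded on a hexagonal grid. The package builds a correspondence cost
    volume (truncated absolute differences and census transform along the three
    epipolar axes) and a defocus cost volume (against a shift-and-sum focal
    stack), refines both with frequency-adaptive multi-scale aggregation and
    superpixel histogram-peak shaping, and fuses them with ground-control-point
    priors into a data term minimized by multi-label alpha-expansion graph
    cuts. Includes optical closed forms for the microscope (resolution limit,
    depth of field, refocus depth per pixel shift), a synthetic hexagonal
    light-field generator with ground-truth disparity for validation, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    yaml,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
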