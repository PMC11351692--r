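Package: arborfract
Title: Fractal Morphometry of Neuronal Arbors on Planar Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the geometry of cultured neurons imaged on planar
    electrode surfaces. Provides tracing of dendritic arbors from
    single-channel fluorescence-style images (thresholding, topology-preserving
    thinning, skeleton-graph extraction with soma-aware traversal rules),
    box-counting fractal dimension with dendrite-width/arbor-width scaling
    cut-offs, convex-hull arbor coverage, normalized process length, glial
    substrate coverage, structure-tensor orientation coherency, and paired
    group comparisons. A synthetic-arbor generator (self-similar trees of
    known similarity dimension, calibration fractals, and multi-segment
    network fields with ground-truth manifests) makes every stage verifiable
    without access to raw microscope images.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
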