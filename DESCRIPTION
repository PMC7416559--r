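Package: ecmarch
Title: Quantification of Extracellular Matrix Fiber Architecture from Electron Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of fibrous extracellular-matrix scaffolds
    imaged by scanning electron microscopy. Segments micrographs into fiber and
    pore phases (trainable pixel classification or thresholding), estimates
    per-fiber diameters from Euclidean-distance-transformed centerlines with
    intersection correction, censuses pores with border and minimum-size
    exclusion, and quantifies fiber orientation and alignment with the
    structure tensor and a nematic order parameter. Also provides cell-shape
    morphometrics (circularity, aspect ratio), tumor-volume calculation,
    storage/loss-modulus crossover analysis of rheology frequency sweeps, a
    fold-change/FDR differential expression screen with biotype filtering, and
    cytokine-array spot normalization. A synthetic-data generator with exact
    ground truth (oriented fibers with von Mises angle dispersion, cell
    outlines, Maxwell-model sweeps, planted expression tables, duplicate-spot
    arrays) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ranger,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    withr,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
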