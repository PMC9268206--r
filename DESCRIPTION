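Package: fibercell
Title: Collagen Fiber Segmentation, Morphometry and Cell-Fiber Spatial
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Segments individual extracellular-matrix fibers from 2-D
    stained-tissue microscopy images, reduces each fiber to a branch-free
    skeleton curve, and computes per-fiber geometric and intensity
    features (length, thickness, angle, intensity, straightness,
    alignment).  Joins single-fiber tables with externally produced
    single-cell tables through radius-based neighborhood counting and
    nearest-object distances, and clusters the resulting spatial profiles
    with Ward linkage.  Includes a synthetic fiber-field generator with
    analytic ground truth for validation, overlay rendering for quality
    control, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
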