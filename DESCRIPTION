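Package: particlecut
Title: Graph-Cut Segmentation and Morphometry of Metallic Particles in
    Electron Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seeded binary segmentation of metallic micro- and nanoparticles
    in scanning electron microscopy (SEM) images by minimum s-t graph cut,
    solved with Dinic's maximum-flow algorithm on a pixel-grid flow network
    built from regional (intensity likelihood) and boundary (neighbor
    similarity) edge capacities.  Includes mask post-processing (hole
    filling, speckle removal, morphological cleanup), per-particle
    morphometry (area, perimeter, circularity, equivalent ellipse, minimum
    bounding rectangle, Feret diameters), segmentation validation metrics
    (Dice, IoU, pixel accuracy), energy-dispersive X-ray (EDS) spectrum peak
    detection with element assignment and peak-height ratios, and a
    synthetic SEM scene and spectrum generator with exact ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    jsonlite,
    grDevices,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    pracma,
    optparse,
    yaml
Config/testthat/edition: 3
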