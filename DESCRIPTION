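Package: cammesh
Title: Intravital Video Analysis of Chick Chorioallantoic Membrane Capillary Meshes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes intravital video recordings of the chick
    chorioallantoic membrane (CAM) microvasculature into the image products
    used to study capillary-mesh remodeling: rigid motion correction by
    normalized cross-correlation of a high-contrast reference square,
    per-pixel temporal standard-deviation vessel images, cumulative
    intensity-change perfusion images, double-threshold vessel segmentation
    with topology-preserving skeletonization and tissue-island extraction,
    skeleton-based network morphometry, and landmark-quadrilateral area
    dynamics. Ships a ground-truthed synthetic CAM scene and video generator
    (polygonal capillary mesh, red-cell particle advection, scripted drift,
    tissue flicker, sensor noise) so the whole pipeline is testable without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
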