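Package: woundmetrics
Title: Wound Perimeter, Area and Volume from Colored 3D Surface Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measurement pipeline for chronic-wound geometry from colored 3D
    surface scans (laser-triangulation range grids or colored PLY meshes).
    The wound edge is delineated on the aligned color image by one of three
    interactive segmentation back-ends (Canny edge pipeline, GrowCut cellular
    automaton, GrabCut-style iterative graph cut). A virtual healthy skin
    (ViHS) surface - a tensor-product B-spline anchored to the minimal-area
    rectangle circumscribed to the wound edge - approximates how intact skin
    would pass over the wound; the measurement is robustified by averaging 31
    ViHS instances obtained by uniformly scattering the rectangle vertices
    within 5 x 5 mm squares. Reported quantities are the wound perimeter and
    area on the ViHS and the volumetric deviation of the wound (VDW), the sum
    of the absolute volumes below and above the ViHS inside the wound edge.
    Includes a synthetic range-scan generator with brute-force ground truth
    for bias experiments, and repeatability reporting utilities (Levene and
    Kruskal-Wallis tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    splines,
    stats,
    grDevices,
    graphics,
    utils,
    jsonlite,
    yaml,
    tiff,
    car
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
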