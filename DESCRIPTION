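Package: zebrakin
Title: Body-Wave Swimming Kinematics of Adult Zebrafish from High-Speed Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies body-wave swimming kinematics of a single adult
    zebrafish from top-view high-speed video. The fish silhouette is
    segmented against a per-pixel temporal median background, its midline
    is skeletonized and resampled to twenty arc-length-uniform control
    points, and three per-frame measurements are derived: unsigned body
    curvature at each control point (degrees of angular change between
    neighbouring midline segments), tail offset (tail-to-centroid distance
    divided by body length), and centroid travel distance. Body-waving
    cycles are normalized to a common frame count, smoothed with zero-phase
    low-pass filters, averaged into spatio-temporal curvature profiles per
    genotype group, and compared against wild-type by Student t tests. A
    parametric undulatory-swimmer simulator with analytic ground-truth
    midlines supports end-to-end validation and phenotype-contrast
    experiments (e.g. muscle-stiffness models of myotonia congenita).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    igraph,
    png,
    tiff,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
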