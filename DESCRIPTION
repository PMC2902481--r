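Package: hnatlas
Title: Reference-Based Delineation of Head-and-Neck Nodal Regions by
    Landmark-Initialized Deformable Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for atlas (reference-subject) based delineation of cervical
    lymph node regions in 3D head-and-neck volumes.  Segments landmark
    structures with constraint-based dynamic thresholding and a 3D active
    contour, estimates dense correspondence between homologous structure
    surfaces, retrieves the most geometrically similar reference subject with
    a weighted feature-space distance built on ICP-aligned Hausdorff mesh
    distances, registers reference to target with a multi-resolution cubic
    B-spline free-form deformation driven by Parzen-window mutual information
    and optionally initialized from surface landmark correspondences, projects
    reference-drawn region masks onto the target, and evaluates results with
    Dice overlap, Hausdorff/mean surface distances, ranking agreement and
    feature-distance correlation.  Includes a synthetic phantom cohort
    generator with known ground-truth deformations for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
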