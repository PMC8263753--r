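Package: valvemorph
Title: Multi-Scale Shape and Structure Analysis of Tri-Leaflet Heart Valves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometric analysis of labeled three-dimensional segmentations of
    tri-leaflet heart valves, developed around the murine pulmonary valve imaged
    by micro-computed tomography. From a labeled voxel volume the package
    identifies the commissure points, free edges and basal attachments of each
    leaflet, builds the annulus (ANL) and sino-tubular junction (STJ) planes,
    and computes the geometric quantities of interest (free-edge and
    basal-attachment lengths, valve height, leaflet thickness, valve perimeter
    and tilt angle) in dimensional and perimeter-normalized form. Leaflet
    mid-surfaces are fitted with tensor-product B-spline (NURBS with unit
    weights) surfaces from which central circumferential and radial
    cross-sections are extracted and normalized into representative shape
    coordinates. Collagen-fiber sets measured in a local microscope frame can be
    mapped into the valve frame and summarized by orientation and diameter
    statistics. A synthetic valve phantom generator with closed-form ground
    truth, and the per-pressure statistical layer (per-pressure mean and
    standard error, linear regression of each quantity against transvalvular
    pressure with a slope t-test), make the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tibble,
    tiff,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
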