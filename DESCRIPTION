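Package: airwaydeform
Title: Pivotal-Plane Airway Geometry Deformation for Maxillomandibular
    Advancement Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for preoperative prediction of upper-airway geometry
    changes after maxillomandibular advancement surgery. Reads, validates,
    smooths and writes STL airway surfaces; applies a C1-smooth pivotal-plane
    free-form deformation of the pharyngeal lumen controlled by per-plane
    anteroposterior (dY) and half-to-peak lateral (dX) enlargement parameters;
    slices meshes with horizontal planes and computes cross-section
    dimensioning quantities (Ys, Yc, width, depth, area); iteratively fits
    deformation parameters to target postoperative widths or areas; computes
    rhinomanometric nasal resistances (including the Ohm's-law parallel
    total); assesses CFD grid-refinement convergence; and exports CFD case
    metadata. Includes a parametric synthetic airway generator with
    analytically known cross-sections so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Matrix,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
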