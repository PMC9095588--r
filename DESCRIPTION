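Package: sphereglide
Title: Analysis of Polar Filament Patterns Gliding on Spherical Vesicle Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of cytoskeletal gliding assays confined to the
    inner surface of giant unilamellar vesicles. Provides sphere geometry and
    equirectangular/hemisphere/z projections of confocal voxel stacks, algebraic
    sphere fitting, arc-length speeds and angular mean squared displacements of
    tracked structures, a patch cross-correlation feature tracker with
    time-averaged surface flow, topological defect bookkeeping (pair angles,
    Poincare-Hopf accounting, tetrahedral/planar configuration classification),
    a rule-based taxonomy of emergent polar patterns (streams, vortices, bands,
    jammed states) with Onsager-criterion density calculations, and seeded
    kinematic generators of ground-truth-labelled synthetic vesicle scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
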