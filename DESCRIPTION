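Package: sheetmech
Title: Mechanics of Collective Cell Migration on Nanopatterned Hydrogels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification chain for collective keratinocyte migration mechanics
    on nanopatterned polyacrylamide hydrogels: particle image velocimetry (PIV) of
    monolayer movies and substrate bead images, regularized Fourier-transform
    traction cytometry (FTTC) on an elastic half-space, monolayer stress microscopy
    (MSM) by two-dimensional force balance, spatial autocorrelation functions with
    threshold-crossing correlation lengths for velocity and stress fields, focal
    adhesion segmentation and tracking (lifetime, area, length, density), sheet
    migration speed, and k-nearest-neighbour interparticle spacing statistics for
    gold nanoparticle arrays. A synthetic-data generator produces every input the
    pipeline consumes with known ground truth, so each stage is testable by
    parameter recovery without experimental recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
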