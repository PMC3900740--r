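Package: diffmap2d
Title: Projection Difference Maps and Sodium-Binding Titrations for 2D
    Electron Crystallography
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing conformational titrations of membrane
    transporters in 2D electron crystallography. Synthesizes sigma-annotated
    projection maps from (h,k) reflection lists, merges multi-lattice
    datasets with phase-origin alignment and amplitude scaling, forms
    difference maps between ion or pH conditions on a common unit cell with
    half-split noise controls, counts peak-to-trough contour levels in
    declared helix regions, and fits the resulting titrations to a
    single-site saturation isotherm to recover apparent Na+ dissociation
    constants and helix displacements. A synthetic two-state crystal
    generator (Gaussian-rod dimer model with occupancy set by a
    proton-competition binding isotherm) provides ground-truth data so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
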