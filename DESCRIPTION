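Package: centriotome
Title: Synthetic Cryo-Electron Tomography and Subtomogram Averaging of
    Centrioles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale cryo-electron-tomography workbench for the 9-fold
    centriole. Builds parametric ground-truth models of triplet and doublet
    microtubule blades with their decorations (pinhead, A-C linker, A-A
    linker, microtubule inner proteins), simulates single-axis tilt series
    with a missing wedge and reconstructs tomograms by weighted
    back-projection, extracts 24 nm disc sub-volumes along the nine rods,
    performs missing-wedge-aware subtomogram alignment and averaging with
    gold-standard Fourier shell correlation, classifies sub-volumes along the
    proximal-distal axis and into partial-B-tubule classes, and quantifies
    whole-centriole flattening, 9-fold geometry, ensemble diameter and blade
    tilt by ellipse fitting and symmetrization.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
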