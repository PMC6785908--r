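Package: lvcoreg
Title: Co-Registration and Morphometry of In-Vivo and Ex-Vivo Cardiac MR
    Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing late-gadolinium-enhancement cardiac MR of
    infarcted left ventricles acquired in vivo with high-resolution ex-vivo
    imaging of the same heart. Provides a synthetic paired left-ventricle
    phantom with a known analytic deformation, scar segmentation by
    full-width-at-half-maximum and mean-minus-SD thresholding with connected
    component seeding, a landmark/rigid/affine/B-spline free-form-deformation
    registration chain operating on label maps, surface-mesh morphometry
    (wall thickness, scar transmurality, nodal scar overlap), voxel-wise
    DICE and compartment volumes, and the associated statistical
    comparisons.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
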