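Package: svhiston
Title: Supervoxel-Based Volumetric Histon Features for Structural MRI
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts supervoxel-based volumetric histon features from
    co-registered grey-matter, white-matter and cerebrospinal-fluid tissue
    probability volumes and classifies subjects (Alzheimer's disease versus
    cognitively normal) with a PCA-reduced linear support vector machine.
    Includes a 3D three-channel SLIC supervoxel segmentation, the histon
    textural feature with a supervoxel-derived similarity threshold, a
    stratified repeated-split evaluation protocol with seven performance
    metrics and McNemar comparison against a voxel-feature baseline, and a
    synthetic brain-phantom cohort generator for end-to-end testing.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
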