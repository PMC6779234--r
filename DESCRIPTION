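Package: zteac
Title: MR-Based PET Attenuation Correction with ZTE Segmentation and a
    Patch-Based 3D U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying MR-based attenuation correction (AC) of
    brain PET. Implements a segmentation-based pseudo-CT method for
    zero-echo-time (ZTE) MRI with a continuous bone-density model, a
    patch-based 3D U-net regressor from ZTE intensity to Hounsfield
    units, conversion of CT-like volumes to 511 keV attenuation maps, a
    desk-scale 2D parallel-beam PET simulator with OSEM reconstruction,
    synthetic paired ZTE/CT/activity head phantoms, and an evaluation
    suite (Dice/Jaccard bone overlap, relative PET error maps, joint
    histograms, VOI tables, repeated-measures ANOVA and post-hoc
    testing) so that AC-map quality and its downstream effect on PET
    quantification can be measured end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    graphics,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    car,
    yaml,
    optparse
Config/testthat/edition: 3
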