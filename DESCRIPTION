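Package: bodycomp
Title: Automated Body-Composition Volumetry from Abdominal CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Fully automated three-dimensional body-composition analysis for
    abdominal computed tomography. Semantic segmentation of CT volumes into
    five body regions (muscle, bones, subcutaneous tissue, abdominal cavity,
    thoracic cavity) with 3D U-Net and multi-resolution U-Net convolutional
    networks trained under sparse (every-fifth-slice) annotation with an
    ignore label, followed by Hounsfield-unit threshold subclassification
    into subcutaneous adipose tissue (SAT), visceral adipose tissue (VAT),
    and muscle, with per-slice volumetry and agreement statistics
    (intra-class correlation, Bland-Altman). Includes a synthetic abdominal
    CT phantom generator with exact ground-truth tissue counts so the whole
    pipeline is testable without patient data, NIfTI and DICOM-series input,
    sliding-window ensemble inference, and cross-validated training with
    AdamW.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
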