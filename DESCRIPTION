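Package: ltpdetect
Title: Detection of Local Tumor Progression on Post-Ablation Liver CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: End-to-end pipeline for detecting local tumor progression (LTP)
    on arterial-phase CT after thermal ablation of hepatocellular carcinoma.
    Converts Hounsfield-unit volumes into a three-channel 8-bit
    representation (liver, ablation and tumor display windows), samples
    labelled 32x32x8 three-channel patches around annotated lesion centers
    with exclusion-sphere negatives, trains a small 3D convolutional network
    classifier, selects the operating threshold on a validation split,
    evaluates per-patch performance (ROC, precision-recall, exact and DeLong
    confidence intervals) and turns above-threshold patches into bounding-box
    region proposals rendered on axial slices. A synthetic post-ablation CT
    phantom generator with known lesion annotations lets the whole pipeline
    be exercised and tested without patient data. Reads DICOM series, NIfTI
    volumes and 3D Slicer fiducial files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    pROC,
    png,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
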