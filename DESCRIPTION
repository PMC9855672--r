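Package: echodsi
Title: Disease-Specific Imaging for Quantitative Ultrasound Breast Lesion
    Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Biophysical feature extraction from raw ultrasound
    radiofrequency (RF), envelope, and log-compressed data for breast
    lesion characterization, and their combination into a single
    probability-of-malignancy score rendered as a color overlay on B-mode
    images ("disease-specific imaging").  Implements H-scan Gaussian
    matched-filter spectral analysis with zone-wise attenuation
    correction, convex-hull boundary roughness, B-scan and boundary-margin
    texture statistics, Burr power-law speckle-amplitude fitting,
    principal-component / projection / Gaussian-kernel support-vector
    scoring with AUC-driven feature-subset selection, an ROC-based
    evaluation protocol with repeated stratified splits and lesion-size
    stratification, and a seeded synthetic RF cohort generator so the
    full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    EBImage,
    grDevices,
    jsonlite,
    minpack.lm,
    png,
    pROC,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
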