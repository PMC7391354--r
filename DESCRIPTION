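Package: radstab
Title: Radiomic Feature Reproducibility Under Segmentation Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how inter-rater variability in lesion segmentation
    propagates into radiomic features extracted from CT images. Simulates
    CT-like lesions with ground-truth masks, generates rater populations whose
    pairwise Dice agreement is calibrated to a target median, extracts an
    89-feature radiomic signature (18 first-order statistics, 12 2D shape,
    22 GLCM, 16 GLSZM, 16 GLRLM and 5 NGTDM texture features) under a fixed preprocessing
    protocol (1 mm isotropic resampling, 25 HU fixed bin width), and estimates
    per-feature reliability with ICC(1,1) from a one-way random-effects model,
    bootstrap confidence intervals, per-category summaries and cross-population
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    grDevices,
    utils,
    EBImage,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
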