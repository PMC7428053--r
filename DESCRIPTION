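Package: ramanidc
Title: Raman Micro-Spectroscopy Classification of Prostate Tissue and
    Intraductal Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnostic classification of prostate tissue from
    confocal Raman micro-spectra: rolling-ball baseline correction of
    substrate and fluorescence background, feature selection with an
    L1-regularized linear support vector machine, Gaussian-kernel SVM
    training with grid search and patient-grouped 5-fold cross-validation,
    frozen-model testing on independent cohorts, ROC operating-point
    selection, and assignment of selected wavenumbers to reference Raman
    peaks of tissue biomolecules. Includes a synthetic cohort simulator
    that emulates tissue-microarray study designs (benign epithelium,
    invasive cancer, intraductal carcinoma of the prostate, high-grade
    prostatic intraepithelial neoplasia, lymphocytes) so the full pipeline
    runs without access to the original spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    e1071,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    glmnet,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
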