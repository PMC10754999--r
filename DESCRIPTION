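Package: spectranet
Title: Multi-Scale Residual 1D Networks for FTIR Serum Spectrum Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for classifying serum Fourier-transform infrared (FTIR)
    absorbance spectra into diagnostic groups with one-dimensional
    convolutional neural networks. Implements four architectures -- a 1D
    AlexNet-style CNN, a 1D ResNet with convolutional-shortcut residual
    blocks, a multi-scale CNN with parallel kernel branches, and the
    multi-scale residual network MSResNet that combines both ideas -- on a
    self-contained, BLAS-backed network engine with Adam optimisation.
    Includes spectra input/output (wide/long CSV and a minimal JCAMP-DX
    reader), replicate averaging and normalisation, a seeded synthetic
    serum-spectrum generator with class-dependent band amplitudes, a
    train/test split plus k-fold cross-validation harness, multiclass
    evaluation (confusion matrices, macro sensitivity/precision/specificity,
    one-vs-rest ROC/AUC), cohort summary statistics, and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
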