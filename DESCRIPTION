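Package: cxrcad
Title: Patch-Based Convolutional Diagnosis of Lung Cancer from Chest Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computer-aided diagnosis pipeline for lung cancer screening on
    chest radiographs. Images are divided into overlapping square patches,
    uninformative patches are filtered with a two-sample t-test contrasting
    lung and non-lung pixel intensities (with an Otsu-thresholding baseline
    selector), and the retained patches are classified by a compact
    five-block convolutional neural network trained from scratch. Evaluation
    uses grouped, label-stratified k-fold cross-validation with patch-level
    and full-image-level metrics. A synthetic phantom radiograph generator
    makes the complete pipeline testable without access to clinical data.
    Readers and writers are included for headerless 16-bit big-endian
    radiograph rasters, PNG/TIFF images, binary lung-field masks, and CSV
    dataset manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
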