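Package: nirhsi
Title: Near-Infrared Hyperspectral Imaging Analysis for Tumor-Margin Delineation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for pixel-wise classification of near-infrared (NIR)
    hyperspectral images of resected tissue specimens, aimed at delineating the
    extent of gastric cancer including regions covered by normal mucosa.
    Provides containers and ENVI-compatible input/output for hyperspectral
    cubes; reflectance and absorbance calibration against white-reference and
    dark-noise frames; standard normal variate (SNV) spectral preprocessing;
    highlight, shadow, necrosis and boundary-margin masking; balanced-sample
    radial-basis-function support vector machine classification with
    median-heuristic bandwidth and leave-one-specimen-out cross-validation;
    pixel-level confusion bookkeeping with region-stratified sensitivity and
    tumor-thickness analysis; and a synthetic specimen generator with a
    two-layer Beer-Lambert mixing model so the whole pipeline is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
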