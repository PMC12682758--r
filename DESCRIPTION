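Package: acukit
Title: Marker Removal, Keypoint Metrics and 3-D Localization for Back
    Acupoint Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and evaluating marker-based back-acupoint
    keypoint datasets. Provides exemplar-based inpainting to erase circular
    adhesive markers from skin images (a classical product-priority baseline
    and an exponential-priority variant with elliptic local patch search),
    restoration-quality metrics (PSNR, global SSIM) and processing-efficiency
    summaries, keypoint accuracy metrics (per-image pixel error, millimeter
    conversion, effective-region hit classification and recall),
    keypoint-consistent augmentation (scale, crop, horizontal flip with
    left/right label swapping), a SimCC sub-pixel coordinate codec with a
    pluggable two-stage detection harness, and the pixel-to-robot-base
    coordinate chain (depth registration, pinhole back-projection, rigid
    transforms). Ships a synthetic-fixture generator so the full stack is
    exercisable without any external imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    withr
LinkingTo:
    Rcpp
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
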