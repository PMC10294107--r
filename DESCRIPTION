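Package: seedseg
Title: Segmentation of Touching Soybean Seeds in Scene Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Splits individual seed images out of multi-seed scene
    photographs of soybeans on a dark background. The pipeline enhances
    the scene with multi-scale retinex with color restoration (MSRCR),
    binarizes it with Otsu adaptive thresholding, locates seeds by tight
    axis-aligned bounding rectangles, detects seeds in physical contact
    from rectangle size, separates tiny contacts by square-kernel
    morphological erosion or by marker-based watershed, and emits
    227x227 crops of each seed. Includes a segmentation-accuracy metric
    (properly segmented outputs over total outputs under one-to-one
    IoU matching), a method/kernel sweep harness, and a deterministic
    synthetic scene generator with per-seed ground truth for
    benchmarking every stage without real photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    fftwtools,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
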