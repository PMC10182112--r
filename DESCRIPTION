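Package: dlratio
Title: Ground-Truth Box Size Conditions for Tumor Detection in Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the size of the square ground-truth region
    of interest (ROI) relative to the tumor -- the D/L ratio, maximum tumor
    diameter over ROI side length -- affects the evaluation of liver-tumor
    detectors on B-mode ultrasound images. Implements the D/L-conditioned
    ground-truth box construction, the preprocessing chain (background margin,
    out-of-bounds elimination, resizing with annotation rescaling,
    horizontal-flip doubling, case-wise 8:2 splitting), a single-threshold
    IoU-based detection evaluation protocol with discriminant-analysis (Otsu)
    threshold calibration, an ultrasound-like phantom generator with four
    liver-lesion appearance archetypes, a detector simulator whose error model
    is conditioned on the training D/L, and the fixed-D/L sweep and
    distributed-D/L experiments that compare training conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
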