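Package: erythema
Title: Quantification of Gastric Ulcer Erythema from RGB Photographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Measures gastric ulcer severity from ordinary RGB photographs.
    Emulates cellophane-film channel shielding, suppresses low-red background,
    segments erythematous tissue by red-value thresholding (with an automatic
    Otsu default), counts lesion pixels, and normalizes them into an ulcer
    index against an untreated control group. Calibrates pixel responses
    against a two-fold serial blood-dilution erythema standard, classifies
    endoscopy-style images by mean RGB severity centroids, scores lesions with
    the conventional length/width clinical rubric, and compares scoring
    methods with per-subject rater deviations and Bland-Altman limits of
    agreement. Includes deterministic, seeded generators for synthetic lesion
    images with ground-truth masks, blood-dilution well plates, and
    multi-rater score panels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    jpeg,
    png,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils
Suggests:
    EBImage,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
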