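Package: coralbof
Title: Bag-of-Hybrid-Visual-Features Classification of Bleached Corals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-level localization of bleached corals in reef survey
    photographs with a bag-of-hybrid-visual-features pipeline: overlapped
    square patch extraction, a hybrid per-patch descriptor combining a
    handcrafted color-texture histogram with a deep patch embedding, a
    class-wise k-means visual vocabulary, thresholded bag-of-features
    histogram encoding, and kernel support-vector classification evaluated
    under repeated stratified K-fold cross-validation. Includes a seeded
    synthetic coral-texture image generator so the complete pipeline can be
    exercised and validated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
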