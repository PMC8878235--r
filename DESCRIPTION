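Package: madpso
Title: Microaneurysm Detection in Fundus Images by Probability-Based
    Discrete Particle Swarm Optimization Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects microaneurysms, the earliest lesions of diabetic
    retinopathy, in retinal fundus photographs. Provides fuzzy-clipped
    contrast-limited adaptive histogram equalization (FC-CLAHE) for
    preprocessing, a probability-based discrete particle swarm optimization
    (PBPSO) clustering algorithm for image segmentation with statistical
    fitness measures (fuzzy entropy, skewness, kurtosis, co-occurrence
    correlation, variance), a normality-based cluster-merge rule, gray-level
    co-occurrence matrix (GLCM) texture features, and a transparent rule-based
    classifier for candidate lesion regions. Includes a ground-truthed
    synthetic fundus phantom generator so the whole pipeline can be exercised
    and evaluated without external image data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    png,
    stats,
    utils
Suggests:
    EBImage,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr,
    tiff
Config/testthat/edition: 3
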