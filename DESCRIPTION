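Package: trabpat
Title: Trabecular Pattern Texture Analysis and Fracture Risk Statistics
        for Panoramic Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Quantifies the mandibular trabecular pattern in fixed-size
        regions of interest from panoramic radiographs and relates it to
        long-term fracture risk. Implements the preprocessing chain
        (3x3 median filter, unsharp self-masking, zero-threshold binary
        segmentation), per-phase segment morphometry (number density,
        area, perimeter, width), a 12-direction line-fraction-deviation
        orientation profile, skeleton strut/node/endpoint statistics,
        and the cohort statistics used for fracture prediction:
        contingency-table odds ratios with Wald intervals,
        sensitivity/specificity, ordinal ROC/AUC, Cohen's kappa, Welch
        t comparison, and forward stepwise logistic regression. A
        seeded synthetic-data module generates trabecular-like oriented
        textures and score/fracture cohorts so the whole pipeline is
        testable without patient radiographs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, png, tiff, jsonlite, Rcpp,
        EBImage
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), pROC, e1071, optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
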