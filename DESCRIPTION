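Package: sphum
Title: Spherically Constrained Optimization for Ordinal Biomarker Combination
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates the optimal unit-norm linear combination of continuous
    biomarkers for discriminating ordered outcome categories by direct
    maximization of the empirical hypervolume under the ROC manifold (EHUM)
    or its upper- and lower-bound surrogates (ULBA), using a derivative-free
    pattern search constrained to the surface of the unit sphere. Includes
    the comparator estimators used in the accompanying simulation study
    (anchored Nelder-Mead, step-down, min-max), scenario generators with a
    train/test replication harness, and clinical post-processing utilities:
    greedy correlation screening, Youden-index cut-points, and stratified
    bootstrap confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
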