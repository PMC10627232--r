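Package: rubriq
Title: Image-Quality Metrics and Significance-Gated Ranking of MRI Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Quantitative and qualitative image-quality assessment of
    candidate MRI sequences (e.g. fat-suppressed T2-weighted protocols for
    MR-guided radiotherapy) and their ranking by a multi-level,
    significance-gated scoring rubric. Computes signal-to-noise and
    contrast-to-noise ratios, slice-wise structure conspicuity from
    millimetre-scale mask morphology, pairwise inter-observer agreement
    (Dice coefficient and 95th-percentile Hausdorff distance), and observer
    grade and comment metrics; applies a distribution-adaptive statistical
    layer (Lilliefors-corrected normality screen, then ANOVA/Tukey or
    Kruskal-Wallis/Dunn) and converts the corrected pairwise significance
    pattern into tiered rank scores that are aggregated per structure and
    per sequence. Includes a seeded digital-phantom generator producing
    multi-sequence, multi-observer studies with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    nortest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
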