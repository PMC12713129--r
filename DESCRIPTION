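Package: rhythmsc
Title: Diurnal Rhythm Detection in Single-Cell Transcriptomic Time Courses
Version: 0.1.0
Authors@R:
    person("Atlas", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect diurnal rhythmicity in single-cell RNA-seq
    time courses sampled at a few Zeitgeber timepoints with biological
    replicates. Provides pseudobulk aggregation with negative-binomial
    Wald testing between timepoints and age groups, a cell-level hurdle
    model with a cellular-detection-rate covariate and a peak-and-trough
    rhythmicity filter, Wilcoxon rank-sum cross-checks and marker calling,
    k-means temporal ordering of samples from small gene signatures,
    fixed- and free-period cosinor fitting for rhythmic binding signals,
    E-box promoter motif scanning, and a synthetic-data generator that
    emulates the assumed experimental design for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
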