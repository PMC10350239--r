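Package: methrel
Title: Probe Reliability for Duplicate DNA Methylation Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates test-retest reliability of DNA methylation array
    probes from technical duplicates. For each probe it computes the
    single-measure, absolute-agreement, two-way random-effects intraclass
    correlation ICC(A,1) from ANOVA mean squares, Bland-Altman limits of
    agreement and their half-width (HoLA), and a modified ICC
    (mICC = ICC - HoLA) that penalises absolute disagreement between
    duplicates. Provides a four-level reliability classification
    (Poor/Fair/Good/Excellent), cross-study concordance utilities
    (classification cross-tabulation, Spearman correlation of reliability
    estimates, rank-based group contrasts, annotation-stratified
    summaries), a synthetic duplicate-data generator with known variance
    components for validation, readers and writers for the tabular
    formats, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
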