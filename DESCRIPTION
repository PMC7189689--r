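Package: methylXCI
Title: Sex-Stratified X-Chromosome Methylation Analysis with XCI Pattern
    Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers X-chromosome inactivation (XCI) related DNA methylation
    patterns from sex-stratified 450K-array beta values in twin cohorts, and
    tests for sex-specific age-associated methylation change. Provides a
    SummarizedExperiment-based cohort container with detection-p masking,
    missingness filtering and blacklist removal; within-sex quantile
    normalization; age-matched sex balancing at twin-pair granularity;
    per-CpG mixed-model sex-difference tests with a twin-pair permutation
    family-wise error rate; two-cohort XCI pattern classification
    (subject-to-XCI, escaping, constitutively high, male-hypermethylated);
    per-sex linear mixed-model age association with Benjamini-Hochberg FDR;
    exact hypergeometric replication tests across cohorts and third-cohort
    validation; and a twin-cohort simulator with known ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    lme4,
    limma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
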