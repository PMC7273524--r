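Package: tpegwas
Title: Exercise-ECG Tpeak-to-Tend Interval Traits and a Two-Stage GWAS Scaffold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives ventricular-repolarization traits (resting Tpeak-to-Tend
    interval and its responses to exercise and recovery) from single-lead
    exercise-stress-test electrocardiograms, and carries them through a
    genetic-analysis scaffold: per-variant additive association with
    trait-specific covariates, two-stage discovery/replication decisions with
    distance-based locus definition, conditional secondary-signal declaration,
    Haseman-Elston estimation of SNP heritability and genetic correlation,
    percent variance explained, and a genetic risk score with a p-value
    threshold scan and logistic validation. Includes synthetic-data generators
    (exercise-test ECGs with known fiducials, genotype cohorts with additive
    architecture, rare binary outcomes) so every stage can be exercised against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    jsonlite,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
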