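Package: proteogps
Title: Polygenic Scores, the Plasma Proteome, and Bidirectional Causal Inference for BMI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking the blood plasma proteome to body mass index (BMI)
    through its genetic drivers: genome-wide polygenic score computation from
    dosage matrices with allele harmonization and cis-window exclusion,
    protein-wide association scans with covariate adjustment, replication
    assessment and subsampling-based replication power, extreme-score
    (tail-effect) stratification with decile summaries, bidirectional Mendelian
    randomization (Wald ratio, inverse-variance weighting with Cochran's Q,
    MR-Egger, two-stage least squares), and a biweight-midcorrelation expression
    screen. A synthetic-cohort generator with known causal structure (Hardy-
    Weinberg genotypes, a polygenic BMI architecture with an optional
    tail-amplified link, and proteins generated under four causal regimes)
    provides ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
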