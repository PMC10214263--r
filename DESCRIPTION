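Package: ipstme
Title: Immunophenotypic Scoring of the Gastric Tumor Microenvironment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for deriving an immunophenotypic score (IPS) from
    bulk tumor expression: non-negative deconvolution of immune-cell
    fractions, resampling consensus clustering into immune phenotypes,
    cross-cohort weighted ranking of phenotype-associated genes,
    transcript-protein concordance filtering, dual feature selection by
    L1-penalized Cox and survival-forest importance, and Youden-cutoff
    risk stratification. Includes immunohistochemistry quantification
    (H-score, pooled cell density, combined positive score, spatial
    immune phenotypes), self-contained clinical test statistics
    validated against enumeration oracles, neoadjuvant
    immune-checkpoint-inhibitor response evaluation, and a seeded
    synthetic-data generator that plants the full ground-truth
    structure so every stage is testable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    glmnet,
    ranger,
    limma,
    MASS,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
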