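Package: bagwas
Title: Brain-Age-Gap GWAS: Simulation, Association, Fine-Mapping and
    Gene Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end toolkit for genome-wide association analysis of
    brain age gap (BAG) phenotypes. Implements stacked cross-prediction
    age estimation with bias-aware BAG computation and reliability
    metrics; per-variant dosage GWAS, fixed-effects inverse-variance
    meta-analysis, stepwise conditional signal selection and cross-trait
    LD clumping; replication sign and binomial tests with winner's-curse
    corrected power; approximate-Bayes-factor credible sets;
    summary-data Mendelian randomization (SMR/HEIDI, GSMR); seven-stream
    gene nomination with a composite priority score; gene-based
    sum-of-chi-square tests and GO enrichment with joint-aspect FWER and
    elim refinement; clumping-and-thresholding polygenic scores. A
    synthetic cohort generator provides genotypes with block LD, imaging
    features, test-retest replicates and omics fixtures so the whole
    pipeline can be exercised without access-restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    glmnet,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
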