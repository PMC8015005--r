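Package: PolyDA
Title: Missing-Value-Aware Differential Abundance Testing for Quantitative Omics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Statistical testing of quantitative omics matrices (label-free
        proteomics, metabolomics) in the presence of missing values. Provides
        five complementary per-feature tests between two conditions: a
        missingness test that couples binomial statistics of missing-value
        counts with an abundance detection-limit scan, an empirical-Bayes
        moderated t-test, rank products (paired natively, unpaired via averaged
        random pairings), a permutation test with low-replicate augmentation,
        and the plain Welch/paired t-test. Per-test false discovery rates
        (Benjamini-Hochberg or Storey q-values) are combined into a unified
        per-feature FDR via Hommel adjustment. Includes a ground-truth
        simulator with abundance-dependent missingness and validation metrics
        (true FDR, sensitivity, ROC, null calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports: methods, stats, utils, S4Vectors, SummarizedExperiment, Rcpp,
        yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), limma, optparse, jsonlite
biocViews: Proteomics, Metabolomics, DifferentialExpression,
        MultipleComparison, StatisticalMethod
Config/testthat/edition: 3
RoxygenNote: 7.3.3
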