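Package: methpred
Title: Predicting Gene Expression from DNA Methylation in Human Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-gene prediction of expression from the DNA methylation of CpG
    probes in the gene region, across individuals in a population. Fits and
    compares three models per gene (best single CpG, all-CpG multiple
    regression, and LASSO penalized regression), estimates out-of-sample
    prediction R-squared by repeated five-fold cross-validation, and provides
    a Fisher z-transformation null distribution and confidence intervals for
    squared correlations. Includes Illumina 450K-style probe-to-gene mapping
    with region groups, handling of SNP-affected and cross-hybridizing (S&C)
    probes, beta/M-value conversion, readers for plain TSV and GEO
    series-matrix layouts, and a synthetic-data generator with known per-gene
    variance explained for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    glmnet,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
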