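Package: sumprs
Title: Polygenic Risk Scores from GWAS Summary Statistics by Penalized
    Regression with Pseudo-AIC/BIC Model Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits polygenic risk score (PRS) models directly from GWAS
    summary statistics and a genotype reference panel, without
    individual-level phenotype data. Penalized regression (LASSO, elastic
    net, and the truncated LASSO penalty) is solved per linkage
    disequilibrium (LD) block by coordinate descent on the summary-statistic
    objective with a regularized LD matrix. Candidate models are compared by
    pseudo-AIC and pseudo-BIC, approximations of the classical criteria
    built from summary-level moment estimates and a split reference panel,
    and by the quasi-correlation, an estimate of out-of-sample predictive
    correlation computable from a testing cohort's summary statistics alone.
    Logistic-regression summary statistics for binary traits can be
    converted to the linear scale. A block-LD genotype and phenotype
    simulator (point-normal and clustered causal effects) supports
    validation end to end, and PLINK 1 bed/bim/fam, LD-block BED, and
    delimited summary-statistic files are read and written natively.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
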