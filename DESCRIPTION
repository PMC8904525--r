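Package: penprs
Title: Penalized and Bayesian Shrinkage Construction of Polygenic Risk
    Scores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds polygenic risk scores (PRS) for case-control traits
    three ways: a unified penalized logistic regression family on
    individual-level genotype dosages whose thresholding operator spans
    the lasso, elastic net, minimax concave penalty and hard-threshold
    (p-value) selection; a "select and shrink" continuous-shrinkage
    Gibbs sampler operating on GWAS summary statistics with a
    block-correlation LD reference; and approximate conditional-and-joint
    stepwise selection from summary statistics. Includes PRS scoring and
    evaluation (AUC, odds ratio per standard deviation, percentile-band
    odds ratios against the middle quintile), absolute-risk projection
    under competing mortality, readers for PLINK and VCF genotypes and
    summary-statistic tables, and a generator of LD-structured synthetic
    case-control panels with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rcpp,
    stats,
    utils,
    vcfR
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
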