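Package: episelect
Title: Prior-Graph-Guided Epistasis Feature Selection for Case/Control
    Genotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Case/control pipeline for interaction-based genetic risk
    modelling: genotype input/output (PLINK bed/bim/fam, VCF), quality
    control (missingness, autosome, two-stage Hardy-Weinberg exact test,
    heterozygosity, identity-by-descent relatedness), per-variant logistic
    association scan, clumping-and-thresholding polygenic risk score
    baseline, a knowledge-graph-guided stochastic search over multi-variant
    genotype-combination hypotheses with multiplicative-weights propensity
    updates, an L1-penalized logistic model over the selected hypothesis
    indicators, and held-out evaluation with bootstrap AUC confidence
    intervals and Youden-optimal operating points. Includes a synthetic
    genotype/phenotype/prior-graph simulator with planted epistatic
    interactions for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
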