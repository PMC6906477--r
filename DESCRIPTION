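Package: wgsblend
Title: Genomic Prediction Blending Chip SNPs with Selected Whole-Genome-Sequence Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Linear mixed-model (pedigree BLUP and one- and two-component GBLUP with
    VanRaden method-1 genomic relationship matrices) and Bayesian four-distribution
    mixture (BayesR-family) genomic prediction for deregressed proofs with
    heterogeneous residual weights, together with the cross-validation machinery
    used in dairy-cattle evaluation: prediction reliability, dispersion bias,
    stability, paired bootstrap contrasts with Bonferroni correction, and an
    equal-SNP-count thinning control. Includes a gene-dropping simulator of
    half-sib structured populations with chip and selected
    whole-genome-sequence SNP panels, deregressed-proof phenotypes governed by
    effective record contributions, imputation-error injection and quality
    control, and reference/validation splitting rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
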