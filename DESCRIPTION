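Package: latentgxe
Title: Latent Genetic Interaction Testing with Multiple Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Kernel-based detection of latent (unobserved) genetic
    interactions in genome-wide association studies using multiple
    correlated traits. A SNP interacting with an unobserved environment or
    genotype induces genotype-dependent trait variances and covariances;
    the package tests for this signature by relating squared trait
    residuals and pairwise residual cross products to genotype with a
    Hilbert-Schmidt independence criterion statistic under linear
    (eigenvalue-weighted, wLIT) and projection (equally weighted, uLIT)
    kernels, aggregated by the Cauchy combination test (aLIT). Includes
    marginal single-column baselines with a principal-component Bonferroni
    correction, genomic-control, linkage-disequilibrium and dominance
    robustness adjustments, a PLINK 1 binary genotype reader and scan
    driver, and a polygenic gene-by-environment simulator for power and
    type-I-error studies. Weighted chi-squared tail probabilities are
    computed by characteristic-function inversion with a saddlepoint
    fallback.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    parallel,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
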