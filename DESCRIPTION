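Package: metGBLUP
Title: Multivariate GBLUP for Multi-Environment Trials with Structured
    Residual Covariance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genomic prediction for multi-environment trials (MET) treating a
    single trait measured in several environments as correlated traits. Fits
    multivariate GBLUP with an unstructured genetic covariance and a choice of
    four residual covariance structures (unstructured, heterogeneous diagonal,
    homogeneous diagonal, first-order antedependence), a compound-symmetry
    genotype-by-environment model, and per-environment univariate GBLUP.
    Variance components are estimated by restricted maximum likelihood
    (quasi-Newton and average-information algorithms) or by Gibbs sampling with
    inverse-Wishart and scaled inverse chi-square priors, including data
    augmentation for missing cells. Includes the VanRaden method-1 genomic
    relationship matrix with marker filters, a synthetic MET generator with
    exact Kronecker-structured genetic and residual covariance, and five-fold
    cross-validation under whole-line (M_CV) and single-environment (S_CV)
    hold-out schemes scored by Pearson prediction ability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr,
    knitr
Config/testthat/edition: 3
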