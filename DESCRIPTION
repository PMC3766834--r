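Package: gherit
Title: Pedigree- and Marker-Based Heritability Estimation for Family Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparing pedigree-based and SNP-based estimates of
    narrow-sense heritability in multi-generation family studies. Builds the
    expected additive relationship matrix A from pedigree records by the
    tabular method, constructs the realized genomic relationship matrix G
    from standardized allele counts after call-rate/MAF quality control and
    binomial Hardy-Weinberg imputation, pre-adjusts quantitative phenotypes
    for fixed covariates by least squares, and fits the additive model
    y = 1*b0 + u + e with u ~ N(0, K*s2u) for K in {A, G} by Gibbs sampling
    under scaled-inverse-chi-square priors. Includes a gene-dropping
    simulator of multi-generation pedigrees with known true heritability,
    so every stage can be exercised against truth, and an end-to-end
    pipeline producing heritability tables, G-vs-A comparisons, and
    predicted-genetic-value correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    yaml,
    ggplot2,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
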