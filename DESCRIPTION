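Package: famendo
Title: Family-Based Endophenotype Analysis of Heritable Expression Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Variance-component analysis of quantitative traits in extended
    families: additive relationship matrices from pedigrees, polygenic mixed
    models fitted by an eigendecomposition rotation with maximum-likelihood or
    REML variance components, heritability tests with the boundary-corrected
    likelihood ratio, BLUP prediction of per-individual genetic values
    ("endophenotypes") for gene-expression traits, kinship-aware association
    scans of endophenotypes against clinical phenotypes, Fisher combined
    p-value joint tests, a multivariate mixed model with Kronecker-structured
    genetic and environmental covariance, gene-length-corrected TMM (geTMM)
    normalization of RNA-seq counts with linear batch removal and PCA
    diagnostics, covariate residualization with rank-based inverse-normal
    transformation, hypergeometric gene-set over-representation with
    Benjamini-Hochberg FDR, and a seeded synthetic-family simulator
    (pedigrees, heritable expression, negative-binomial counts, pleiotropic
    phenotypes) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    yaml,
    limma,
    edgeR
Suggests:
    testthat (>= 3.0.0),
    broom
Config/testthat/edition: 3
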