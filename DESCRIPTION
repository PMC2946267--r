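Package: hapepi
Title: Haplotype-Haplotype Epistasis Mapping with Adaptive LASSO Logistic
    Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Detects epistatic interactions between two-SNP haplotype blocks
    in case-control data. Unphased genotypes are collapsed to composite
    diplotypes relative to a candidate "risk" haplotype, the phase-ambiguous
    double heterozygote is handled as a two-component mixture inside an EM
    loop, and the eight Cockerham-coded genetic effects (additive, dominance
    and their four interactions) are estimated by adaptively weighted
    L1-penalized logistic regression solved with a maximum-violator
    Gauss-Seidel coordinate algorithm. Includes BIC-based tuning and risk-
    haplotype selection, permutation p-values for selected effects, and a
    simulation harness for type-I error and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
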