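Package: slpburden
Title: Weighted Rare-Variant Burden Tests and Pathogenicity-Predictor
    Benchmarking with Signed Log P-Values
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Gene-based weighted burden association testing for rare coding
    variants in case-control cohorts, and a harness for benchmarking variant
    pathogenicity predictors against each other. Variants are classified into
    loss-of-function and protein-altering categories from consequence terms,
    filtered to minor allele frequency at most 0.01, and weighted so that
    rarer variants receive higher weights. Per-individual gene burden scores
    (category indicators or predictor scores, times dosage and frequency
    weight) enter a covariate-adjusted logistic regression; the Wald test on
    the predictor burden is summarized as a signed log10 p-value (SLP),
    positive when higher burden associates with case status. A multi-gene,
    multi-predictor comparison produces the SLP matrix with per-predictor
    means, per-gene relative SLP scalings, and the predictor-score
    correlation matrix. A synthetic cohort generator with a latent
    true-pathogenicity model makes the whole pipeline testable without access
    to restricted biobank data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
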