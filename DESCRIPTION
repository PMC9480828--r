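Package: germcore
Title: Core Collection Construction for Mixed-Type Germplasm Phenotypes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building and evaluating core collections from
    germplasm phenotype tables that mix quantitative and qualitative traits
    and carry substantial missingness. Implements two-stage chained-equations
    multiple imputation with predictive mean matching and Bayesian
    multinomial-logit draws, Gelman-Rubin convergence diagnostics,
    entropy-weighted k-means clustering of mixed-type data, Shannon-Weaver
    and Nei phenotypic diversity indices, Sturges-rule trait classification
    with a maximization-strategy (class-coverage) core selector, a
    five-index representativeness evaluation (MD%, VD%, CR%, VR%,
    Coverage%), a modified Roger's distance for phenotype vectors, and a
    synthetic germplasm generator with latent cluster structure and
    missing-at-random masking for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    nnet
Config/testthat/edition: 3
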