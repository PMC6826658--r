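Package: ssgblup
Title: Single-Step Genomic Evaluation of Repeated-Measure Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic evaluation toolkit for repeated-measure traits in
    livestock, built around the single-trait repeatability animal model.
    Provides pedigree machinery (numerator relationship matrix A, sparse
    Henderson inverse, inbreeding by the Meuwissen-Luo recursion), genomic
    relationship matrices (VanRaden G with quality control and blending),
    single-step H-inverse assembly, mixed-model-equation solvers with
    prediction error variances, average-information REML estimation of
    variance components (single-trait and bivariate), de-regressed proofs
    with parent-average removal, cross-validation and forward-prediction
    assessment of predictive ability, and a gene-dropping simulator that
    generates pedigrees, genotypes and repeated phenotype records for
    method validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
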