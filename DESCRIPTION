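Package: defectEval
Title: Single-Step Genetic Evaluation of Binary Morphological Defect Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for single-step (pedigree plus genomic) genetic evaluation of
    binary morphological defect traits in livestock. Fits linear and threshold
    (liability) animal models by Gibbs sampling with an H-inverse prior on
    additive effects, builds pedigree (A), genomic (G) and combined (H-inverse)
    relationship matrices, converts heritabilities between the liability and
    observed scales, transforms breeding values to the liability and probability
    scales by two alternative adjustments, and compares models through rank
    correlations and top-fraction sire concordance. A synthetic-population
    generator (multi-generation pedigrees, gene-dropped SNP genotypes,
    liability-model binary phenotypes with contemporary-group structure)
    makes every stage testable without proprietary herd data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
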