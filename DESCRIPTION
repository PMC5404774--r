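Package: snpconsensus
Title: Consensus SNP Selection for Continuous Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An iterative random-forest filtering and consensus feature
    selection pipeline for identifying key single nucleotide polymorphisms
    (SNPs) associated with continuous phenotypes in high-dimensional (p > n)
    candidate-gene association data. Genotypes coded 1/2/3 (major homozygous,
    heterozygous, minor homozygous) are filtered to a top-k set by permutation
    variable importance from regression forests over an increasing tree
    schedule, then screened by an ensemble of forward stepwise, ridge and
    lasso regression plus a shadow-feature (Boruta-style) all-relevant
    selector. SNPs flagged by at least three of the four methods in the final
    iteration form the consensus key-SNP set, and a cross-iteration frequency
    based confidence score separates likely true positives. Includes a
    Hardy-Weinberg synthetic genotype/phenotype generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ranger,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
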