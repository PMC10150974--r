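Package: gwaswd
Title: Case-Control GWAS Classification with Hybrid Feature Selection
    and Wide-and-Deep Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for classifying case-control status
    from genome-wide SNP genotypes. Reads and writes PLINK 1 binary
    triplets (bed/bim/fam), simulates diploid biallelic cohorts with
    linkage disequilibrium and planted causal effects, applies the
    standard quality-control cascade (missingness, sex check, autosome
    and minor-allele-frequency filters, exact Hardy-Weinberg tests,
    pi-hat relatedness), screens variants with per-SNP logistic
    regression, encodes genotypes as one-hot indicators, selects
    features with a hybrid of principal-component loadings and the
    Boruta shadow-feature algorithm, expands selections with
    map-adjacent neighbour SNPs, and trains random-forest, wide, deep
    and wide-and-deep neural-network classifiers with decision-rule
    extraction from the best forest tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    randomForest,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    rpart,
    optparse
Config/testthat/edition: 3
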