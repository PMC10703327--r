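Package: ashfst
Title: Allele-Sharing Moment Estimators of Global, Population-Specific and
    Population-Pair FST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Moment estimators of FST built from allele-sharing matrices:
    population-specific values, the full population-pair matrix, overall FST,
    pairwise FST, kinship and individual inbreeding coefficients, for genotype
    dosage data of any ploidy. Includes a coancestry-recursion engine that
    predicts expected FST under an arbitrary backward migration matrix
    (continent-island, finite island, stepping stone and river models as
    special cases), a forward Wright-Fisher metapopulation simulator of
    unlinked biallelic loci, reference-point transformations between the
    mean-between, minimum-between and constant-reference scales, and an
    evaluation harness (RMSE, subsampling, block bootstrap, and an independent
    Weir-Cockerham oracle).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    vcfR
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
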