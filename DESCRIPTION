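Package: ricesalt
Title: Stage-Specific Salinity-Tolerance Screening and Allele Mining for Rice Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying stage-specific salinity tolerance in rice
    diversity panels from replicated control/stress phenotype trials. Computes
    per-trait stress tolerance indices (STI), membership-function values (MFV)
    and the average membership-function value (AMFV) used to classify genotypes
    into five tolerance classes, and tracks class transitions across
    developmental stages. Fits cross-validated LASSO/ridge/elastic-net models
    that predict the multi-trait tolerance score from trait indices, runs
    single-marker association scans with Bonferroni control on quality-filtered
    SNP matrices (VCF or HapMap), and mines favourable alleles, homozygous
    multilocus combinations and candidate-gene windows around significant SNPs.
    Includes a synthetic-data generator that emulates the replicated two-stage
    trial design with planted additive causal loci, so the whole pipeline is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    yaml
Suggests:
    car,
    glmnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
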