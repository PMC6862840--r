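Package: ldlapca
Title: Combined Linkage and Linkage Disequilibrium QTL Mapping with
    Principal Component Compression of IBD Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: QTL mapping for family-structured livestock populations by
    combined linkage and linkage disequilibrium analysis (LDLA). Gametes of
    genotyped individuals are phased and classified into base haplotypes
    (inherited from ungenotyped parents) and replicated haplotypes;
    identity-by-descent probabilities between base haplotypes are estimated
    from marker windows, descent of replicated haplotypes is traced through
    the pedigree, and the resulting IBD matrices are compressed by principal
    component analysis. QTL and polygenic effects are then estimated as
    fixed effects in a reliability-weighted least-squares scan with
    permutation-based genome-wide significance thresholds and
    correlation-based clustering of significant positions into QTL regions.
    Includes a family-structured population simulator providing ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
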