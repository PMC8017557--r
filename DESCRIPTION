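Package: pleioscan
Title: Pleiotropy Scanning in Multibreed Populations via Weighted
    Single-Step GBLUP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Single-step genomic BLUP machinery for detecting pleiotropic
    genomic regions in multibreed livestock populations. Builds pedigree
    (A), genomic (G) and joint (H) relationship matrices with inbreeding,
    estimates variance components by average-information REML for single-
    and two-trait animal models, runs the iterative weighted single-step
    GWAS (nonlinearA marker weights, 1-Mb window variance shares) with
    conditional covariate adjustment, classifies cross-trait overlapping
    windows into pleiotropic and suggestive regions, and flags candidate
    genes from top-ranked markers against a local annotation. Includes a
    gene-dropping simulator of multibreed pedigrees, genotypes and
    correlated traits so the whole pipeline is testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    data.table,
    Matrix,
    MASS,
    GenomicRanges,
    IRanges,
    rtracklayer,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
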