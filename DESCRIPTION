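Package: psrrr
Title: Pathway Group-Lasso Sparse Reduced-Rank Regression for Multivariate
    Imaging Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint multilocus pathway analysis of genome-wide SNP data against a
    multivariate quantitative (imaging) phenotype. SNPs are mapped to genes and
    overlapping gene pathways, the design matrix is expanded so pathways form
    disjoint blocks, and a rank-1 sparse reduced-rank regression with a weighted
    group-lasso penalty selects associated pathways. Includes adaptive pathway
    weight tuning against selection bias under the permutation null,
    half-sample resampling to rank pathways, SNPs and genes by selection
    frequency, a second-stage lasso for SNP/gene selection, longitudinal
    voxelwise phenotype extraction (slope fitting, ANCOVA screening with
    Bonferroni voxel selection, covariate residualisation), genotype quality
    control with an exact Hardy-Weinberg test, PLINK and GMT input/output, and
    a synthetic-data generator for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    Rcpp
LinkingTo: Rcpp
Suggests:
    jsonlite,
    RNifti,
    tidyr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
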