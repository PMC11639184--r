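Package: permlmm
Title: Population-Aware Permutation Significance Thresholds for Linear Mixed Model GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Genome-wide association studies with linear mixed models and
    Westfall-Young maxT permutation-based significance thresholds. Permutations
    can be population-aware: instead of shuffling the phenotype (which breaks
    the relatedness encoded in the kinship matrix), the rows of the fixed-effects
    matrix are permuted, which is provably equivalent to permuting the phenotype
    together with the covariance matrix. A spectral decomposition of the kinship
    matrix and a block decomposition of the normal equations make batch-wise and
    permutation-wise scans efficient. Includes readers for PLINK bed/bim/fam,
    VCF and delimited genotype matrices, a Balding-Nichols structured-genotype
    simulator, a phenotype simulator with fixed heritability and causal-marker
    explained variance under Gaussian or Gamma noise, and a phenotype-wise
    false-discovery-rate evaluation protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    tibble,
    dplyr,
    purrr,
    rlang,
    readr,
    withr,
    ggplot2,
    generics,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    cluster,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
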