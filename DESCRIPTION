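Package: lactsnp
Title: Candidate-Gene SNP and Haplotype Association Analysis for Milk
    Production Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for candidate-gene association studies of
    milk production traits in dairy cattle half-sib designs. Provides
    genotype and allele frequency summaries with Hardy-Weinberg chi-square
    tests, pedigree-based additive relationship matrices and their sparse
    inverses, pairwise linkage disequilibrium (D-prime with likelihood
    confidence intervals), Gabriel-style haplotype-block detection, EM
    haplotype frequency estimation with per-animal diplotype assignment,
    single-SNP and haplotype-combination association testing under an
    animal model fitted by REML through Henderson's mixed-model equations,
    additive/dominance/allele-substitution effect decomposition,
    per-gene Bonferroni correction, and allele-differential transcription
    factor binding-site scanning with JASPAR position weight matrices.
    A synthetic-cohort generator emulating a paternal half-sib dairy
    design supports parameter-recovery testing of the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
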