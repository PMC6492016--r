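Package: prsvm
Title: Polygenic Risk Scores Versus Kernel Support Vector Machines for
    Case-Control Genotype Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates case-control genotype cohorts with additive polygenic
    and XOR-epistatic disease architectures, applies a standard GWAS quality
    control stack (hard-calling, missingness, minor allele frequency and
    Hardy-Weinberg filters, region exclusion, association-aware LD pruning,
    multinomial imputation of missing genotypes), and compares polygenic risk
    scoring against soft-margin support vector machines with linear and
    radial basis function kernels under a repeated 75/25 train/test split
    protocol with Monte-Carlo hyperparameter search. Also implements a
    two-SNP simulation study of the correlation induced between independent
    disease-associated loci by retrospective case-control sampling, and the
    resulting power advantage of the single-score test over multivariate
    logistic regression.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
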