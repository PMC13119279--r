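Package: germcore
Title: Genetic Diversity Analysis and Core Germplasm Collection Construction
Version: 0.1.0
Authors@R: person("Germcore", "Developers", role = c("aut", "cre"),
    email = "maintainers@germcore.dev")
Description: Tools for SNP-based germplasm characterisation and two-track
    core-collection construction. Reads multi-sample VCF genotype panels,
    applies GATK-style hard filters, minor-allele-frequency filtering and
    PLINK-style linkage-disequilibrium pruning, and computes the standard
    population-genetic diversity parameters (observed and expected
    heterozygosity, nucleotide diversity, polymorphism information content,
    inbreeding coefficient), pairwise Weir-Cockerham Fst with gene-flow
    conversion, identity-by-state and Modified Rogers distances,
    neighbor-joining trees, principal component and principal coordinate
    analyses, and kinship matrices. Core subsets are selected by maximising
    the average entry-to-nearest-entry distance at gradient sampling
    fractions (genotype track) or by phenotype representativeness scored
    with mean difference, variance difference, coincidence rate of range
    and variable rate of coefficient of variation (phenotype track), then
    merged and validated by ANOVA with Tukey post hoc tests. A
    Balding-Nichols synthetic-panel generator provides ground-truthed data
    for testing and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse,
    knitr
Config/testthat/edition: 3
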