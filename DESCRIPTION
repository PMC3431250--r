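Package: ldstructure
Title: Linkage Disequilibrium, Haplotype Blocks, Effective Population
    Size and Inbreeding from SNP-Array Data
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genome-structure analysis for diploid autosomal SNP-array
    panels genotyped under a half-sib daughter design (few sires, many
    daughters), as used in dairy livestock populations. Provides
    two-stage genotype quality control (per-individual then per-marker
    call-rate, minor-allele-frequency and exact Hardy-Weinberg filters)
    with an auditable ledger, Mendelian-inconsistency cleaning against
    sires and iterative sire/frequency-based imputation, rule-based
    pedigree haplotype deduction, pairwise linkage disequilibrium (D'
    and r-squared) with Gabriel-style confidence bounds and
    haplotype-block calling, LD-decay summaries and the half-length of
    r-squared, historical effective population size from binned LD via
    the Sved relationship with configurable centimorgan-per-megabase
    conversion, pedigree inbreeding by the Meuwissen-Luo algorithm,
    three marker-based inbreeding estimators (additive-variance, excess
    homozygosity, correlation of uniting gametes), and a forward-in-time
    Wright-Fisher simulator with recombination, declining effective-size
    trajectories, array-like ascertainment and half-sib sampling that
    emits genotypes, true phase, pedigree and a truth ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: SNP, LinkageDisequilibrium, PopulationGenetics, QualityControl
RoxygenNote: 7.3.3
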