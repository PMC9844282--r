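Package: prsport
Title: Polygenic Score Construction and Cross-Cohort Portability Evaluation
    for Sleep Traits
Version: 0.1.0
Authors@R:
    person("prsport", "developers", email = "prsport@example.org",
           role = c("aut", "cre"))
Description: Builds polygenic risk scores (PRS) for questionnaire sleep
    traits (sleep duration, chronotype, insomnia) from GWAS summary
    statistics and evaluates their portability in an independent target
    cohort. Covers summary-statistic quality control and allele
    harmonization, target-cohort genotype and sample QC (heterozygosity
    outliers, genomic-relationship-based relatedness pruning), LD pruning
    and principal components for population structure, greedy p-value
    ordered LD clumping, weighted allele-dosage scoring, and
    covariate-adjusted evaluation (incremental R-squared, McFadden
    pseudo-R-squared, extreme-tail contrasts). Ships a two-cohort
    genotype/phenotype simulator with LD blocks and fixed heritability so
    the whole pipeline is testable without restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    VariantAnnotation,
    withr
Config/testthat/edition: 3
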