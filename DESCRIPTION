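Package: chipcohort
Title: Clonal Hematopoiesis Annotation and Cohort Association Analysis
Version: 0.1.0
Authors@R: person("chipcohort", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Rule-based annotation of clonal hematopoiesis of indeterminate
    potential (CHIP) and lymphoid driver variants from annotated somatic
    variant tables (whole-exome or targeted-panel mode), an automated
    SNP-array intensity outlier caller for CHIP hotspot loci with
    locus-qualification heuristics and sequencing-concordance analysis,
    and the epidemiological layer used in biobank studies of CHIP:
    endpoint harmonization from dated registry events, covariate-adjusted
    logistic and Cox proportional-hazards association models,
    Kaplan-Meier/log-rank comparisons, and group tests. A seeded synthetic
    cohort generator emulates all three input kinds (variant tables,
    array intensities, phenotype/registry tables) with known ground truth
    for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
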