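Package: aneuscore
Title: Genome-Wide Aneuploidy Scores from Chromosome-Arm Read Counts and
    Their Prognostic Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes mFast-SeqS-style genome-wide aneuploidy scores from
    chromosome-arm read counts of shallow cell-free DNA sequencing: per-arm
    Z-scores against a healthy reference panel, their squared sum, and a
    panel-standardized genome-wide Z-score with dichotomization at a
    configurable threshold. Includes ingestion of aligned reads (SAM/BAM)
    or precomputed count tables with the assay's mapping-quality and
    arm-exclusion filters, Kaplan-Meier/log-rank and Cox
    proportional-hazards analyses of the dichotomized score (univariate
    screen, backward selection, combined biomarker strata), data-driven
    cutpoint optimization with bootstrap resampling, rank correlations
    with orthogonal tumour-burden markers, a power calculation for
    required events, and a synthetic-cohort generator with known truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    Rsamtools,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
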