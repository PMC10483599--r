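# aneuscore

Genome-wide aneuploidy scores from shallow cell-free DNA (cfDNA)
sequencing, and their prognostic survival analysis.

Liquid-biopsy assays that amplify LINE-1 retrotransposon elements with a
single primer pair (the mFast-SeqS family) sample every chromosome arm at
once from ~1 ng of plasma cfDNA. In a tumour-bearing patient the
circulating tumour DNA (ctDNA) fraction distorts the relative
representation of arms according to the tumour's copy-number profile, so
a genome-wide summary of arm-level imbalance is a cheap proxy for ctDNA
burden — and, dichotomized, a prognostic biomarker in metastatic
castration-resistant prostate cancer (mCRPC) comparable to the
established circulating-tumour-cell (CTC) count. This package implements
that pipeline end to end for analysts working with arm-level count data:

1. **Arm counting** — aligned single-end reads (SAM/BAM, hg19) are
   filtered (unmapped, secondary/supplementary, MAPQ < 15 dropped) and
   assigned to the chromosome arm containing their leftmost aligned base.
   The LINE-1-poor arms 13p, 14p, 15p, 22p and all of chromosome Y are
   excluded; samples with fewer than 90,000 retained reads are flagged
   for re-sequencing. Precomputed arm-count tables (TSV) are equally
   accepted.
2. **Scoring** — per-arm normalized fractions `f_a = n_a / N` are
   standardized against a healthy reference panel (n = 17 by
   convention): `z_a = (f_a − μ_a) / σ_a`. The squared Z-scores are
   summed into the genome-wide aneuploidy score `S = Σ_a z_a²`, which is
   in turn standardized against the panel's own score distribution,
   `G = (S − μ_S) / σ_S`; samples with `G ≥ 5` are called aneuploid
   (ctDNA detectable).
3. **Survival analysis** — Kaplan–Meier curves, log-rank tests, and Cox
   proportional-hazards models (Efron ties) of overall survival on the
   dichotomized aneuploidy score, dichotomized CTC count (< 5 vs ≥ 5 per
   7.5 mL), WHO status and routine labs: univariate screen (retain
   P < 0.1), backward selection (drop at P ≥ 0.1), and the combined
   2 × 2 CTC-by-aneuploidy strata that isolate the worst-prognosis
   group. Hazard ratios carry Wald 95% CIs and partial-likelihood AIC;
   Schoenfeld's required-events formula is included for power planning.
4. **Cutpoint optimization** — a data-driven alternative dichotomization
   threshold maximizing sensitivity + specificity against survival
   status, with seeded bootstrap resampling of its variability.
5. **Associations** — Spearman correlation (two-sided, t-approximation)
   of the score with orthogonal ctDNA-burden markers (maximum variant
   allele frequency, CTC count), plus a descriptive least-squares line.
6. **Synthetic cohorts** — a generative model (Dirichlet-multinomial arm
   counts shifted by tumour fraction under per-arm copy numbers,
   negative-binomial CTC counts rising with tumour fraction, exponential
   survival with configurable log-hazard ratios, independent censoring)
   with full ground truth, so every stage is testable without any
   external download.

## Worked example

Simulate a discovery-style cohort (17 healthy controls, 131 patients,
generative hazard ratios 3.24 for aneuploidy and 2.92 for CTC ≥ 5) and
run the whole pipeline:

```r
library(aneuscore)

cfg    <- simulation_config(seed = 42)
cohort <- simulate_cohort(cfg)
res    <- run_pipeline(cohort$patients, cohort$reference, cohort$clinical,
                       arms = cohort$arms, n_boot = 1000, seed = 42)
res
#> <aneuscore_summary> 131 patients (98 events), 72 aneuploid
#> Multivariable model:
#> <cox_fit> n = 131, events = 98, ties = efron, AIC = 742.60
#>   alb                    HR 1.06 (95% CI 1.01-1.12), p = 0.0296
#>   alp                    HR 1 (95% CI 1-1), p = 0.0418
#>   aneuploid              HR 3.26 (95% CI 1.96-5.45), p = 5.79e-06
#>   ctc_high               HR 1.92 (95% CI 1.22-3.01), p = 0.0045
#> Cutpoint: 2.87927 (Youden 0.361)
#>   score_vs_max_vaf: rho = 0.854
#>   score_vs_ctc: rho = 0.465
```

Reading the output: after backward selection, being called aneuploid
(standardized genome-wide Z-score ≥ 5) multiplies the death hazard by
3.26 independently of a high CTC count (HR 1.92) and the retained labs —
the simulated cohort reproduces the qualitative finding that both
liquid-biopsy markers are independent prognostic factors. The
dichotomization split is stark in absolute terms too:

```r
km <- res$km$aneuploid
km[["FALSE"]]$median   # 27.1 months median OS, euploid patients
km[["TRUE"]]$median    #  5.1 months, aneuploid patients
```

The data-driven cutpoint (2.88 here, bootstrap median 2.88 with a wide
95% interval) sits well below the conventional threshold of 5 — exactly
the behaviour reported for this assay, where threshold re-optimization
trades specificity for sensitivity.

Individual stages are exported on their own: `load_arm_definitions()`,
`count_reads_per_arm()`, `build_reference()`, `arm_zscores()`,
`genome_wide_score()`, `score_cohort()`, `km_estimate()`,
`logrank_test()`, `cox_fit()`, `univariate_screen()`,
`backward_selection()`, `combined_strata_fit()`, `required_events()`,
`optimize_cutpoint()`, `spearman_assoc()`. See the vignette
(`vignettes/aneuploidy-scoring.Rmd`) for the model and every design
choice.

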