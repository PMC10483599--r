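---
title: "Genome-wide aneuploidy scoring from arm-level cfDNA counts: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide aneuploidy scoring from arm-level cfDNA counts: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its statistical model, the
defaults it ships, and the design decisions taken where the method as
published in the liquid-biopsy literature leaves room.

## The measurement model

A LINE-1 single-primer amplicon assay samples reads from every
chromosome arm roughly in proportion to the arm's content of LINE-1
elements. For a plasma sample containing a tumour fraction $f$ of ctDNA
whose tumour has per-arm integer copy numbers $c_a$ (diploid $c_a = 2$),
the expected relative weight of arm $a$ is

$$ w_a' \propto w_a \cdot \frac{2(1-f) + f\,c_a}{2}, $$

renormalized over the analyzed arms, where $w_a$ is the healthy
(diploid) arm weight. At $f = 0$ this reduces exactly to the healthy
model; at $f = 1$ an arm at copy 4 doubles its relative weight before
renormalization. The assay therefore observes copy-number signal only
through *relative* arm representation, which is why all scoring below is
depth-invariant.

### Arm counting

Reads are filtered — unmapped, secondary and supplementary records, and
mapping quality below 15 are dropped — and each remaining read is
assigned to the arm containing its leftmost aligned base (0-based
half-open arm intervals; 150 bp single-end amplicon reads never straddle
a centromere in practice, so no split handling is needed). PCR
duplicates are *kept*: the assay is amplicon-based and deduplication
would collapse the signal. The LINE-1-poor short arms of the acrocentric
chromosomes 13, 14, 15 and 22, and chromosome Y, are excluded; 42 of the
48 arms of chr1–22 + X + Y remain.

Three choices here are ours where the published method is silent:

* **21p is not excluded by default**, although chromosome 21 is
  acrocentric too — the canonical exclusion list names only 13p, 14p,
  15p, 22p and chrY. `default_excluded_arms(exclude_21p = TRUE)`
  restores the conservative variant.
* **The normalization denominator** is the sum over *included* arms
  only, so the normalized vector is a probability vector over the
  analyzed arms; reads on excluded arms are tallied but never enter
  totals.
* **The 90,000-read re-sequencing flag** is evaluated on the retained
  (mapped, MAPQ-passing) read count *before* arm exclusion, since it is
  a library-yield criterion, not a scoring one.

### Scoring

With normalized fractions $f_a = n_a/N$ and a healthy reference panel
(by convention $n = 17$ diploid subjects) supplying per-arm mean
$\mu_a$ and standard deviation $\sigma_a$ (sample SD, $n-1$
denominator — the standard unbiased choice for a small panel):

$$ z_a = \frac{f_a - \mu_a}{\sigma_a}, \qquad S = \sum_a z_a^2 . $$

`genome_wide_score()` implements exactly this raw sum with an
**inclusive** dichotomization boundary ($S \ge$ threshold is
aneuploid). No per-arm truncation or pre-filtering is applied before
squaring and summing; variants of the assay that zero small $|z_a|$
first are available through `per_arm_z_min` but off by default.

**Why a second standardization exists.** Because every $z_a$ is
standardized, $S$ concentrates near the number of analyzed arms for a
*healthy* sample (about 50 for 42 arms after small-panel inflation) —
the raw sum cannot be compared against a fixed threshold of 5 on
full-genome profiles. The assay's threshold is calibrated on the
*panel-standardized* genome-wide Z-score

$$ G = \frac{S - \mu_S}{\sigma_S}, $$

where $\mu_S, \sigma_S$ are the mean and SD of the panel controls' own
(resubstitution) scores, computed by `build_reference()`. Healthy
samples then sit near $G = 0$ and the conventional $G \ge 5$ call has a
small, stable false-positive rate. `score_cohort()` reports both $S$ and
$G$ and dichotomizes on $G$ by default (`standardize = FALSE` gives the
raw-sum rule). "Aneuploidy score" and "genome-wide Z-score" are used
interchangeably in this literature; this package treats the thresholded
quantity as $G$ and always reports the raw $S$ alongside.

The alternative published-style threshold (e.g. 1.9227...) is a plain
parameter everywhere — nothing is hard-coded beyond the default of 5.

## Survival analysis

Overall survival is modelled with the Cox proportional-hazards partial
likelihood, **Efron tie correction by default** (the convention of the R
survival ecosystem in which these analyses are usually run; Breslow is a
flag and coincides with Efron on tie-free data). Confidence intervals
are Wald, $\exp(\beta \pm 1.96\,\mathrm{SE})$, as universally reported
in this literature; AIC is $2k - 2\log PL$ with $k$ the number of
$\beta$ terms. Missing covariate values are handled complete-case per
model with counts recorded.

The modelling workflow mirrors standard biomarker practice: a
univariate Cox screen over the baseline characteristics (age, Gleason,
PSA, WHO 0 vs 1–2, albumin, neutrophils, haemoglobin, WBC, ALP, LDH,
dichotomized aneuploidy, dichotomized CTC) retaining $P < 0.1$; then
backward selection dropping the single largest Wald $p \ge 0.1$ per
refit — deterministic given the data, and returning an explicit empty
model rather than an error if everything is removed. The combined
2 × 2 strata use CTC < 5 & euploid as reference and fit three indicator
terms; under the generative additive log-hazards the double-positive
group's HR is the product of the marginal HRs, which the tests assert.

Dichotomized covariates (`ctc_high`, `who_high`) are always recomputed
from the raw values at load time, never trusted from input columns.

`required_events()` is Schoenfeld's formula
$D = \lceil (z_{1-\alpha/2} + z_{\text{power}})^2 / (p(1-p)\ln^2 HR)
\rceil$. Published power statements of the "minimum of 32 events" kind
depend on an HR and group split that are rarely printed; the function
takes them as explicit arguments and asserts nothing about any
particular published count.

## Cutpoint optimization

`optimize_cutpoint()` maximizes sensitivity + specificity (the argmax is
identical to Youden's index) for classifying survival status at end of
follow-up — dead vs alive, deliberately ignoring follow-up time, which
is how this style of cutpoint is defined; it is a known simplification
and the reason the result should be read as exploratory. Candidate
thresholds are the midpoints between consecutive distinct scores plus
$\pm\infty$ sentinels, which enumerate every achievable classification
(`candidates = "observed"` switches to the observed values themselves,
the style that produces thresholds printed to nine decimals). Ties are
broken toward the smallest threshold. The direction — higher score
predicts death — is fixed a priori by the biology; no automatic
direction search. The bootstrap (default 10,000 replicates, seeded)
resamples patients with replacement and records each replicate's
optimum, summarized by median and 2.5/97.5 percentiles; replicates that
happen to draw a single survival class yield `NA` and are excluded from
the summary rather than redrawn, keeping the seed arithmetic trivially
reproducible. No bias-corrected interval is attempted.

## Associations

Spearman's $\rho$ with average-rank ties and the two-sided
t-approximation on $n-2$ df — adequate at cohort sizes in the hundreds;
for $n \le 10$ the tests use exhaustive hand-rank oracles instead. The
descriptive least-squares line regresses the second-named marker on the
aneuploidy score (the published "(x ~ y)" notation leaves the response
ambiguous; we fix score-as-x and document it). Rank correlation is
invariant to the signed-log display transforms these figures are usually
drawn with, so $\rho$ is computed on raw values.

## The synthetic-data generator

`simulate_cohort()` exists so that every downstream stage has a
ground-truth oracle. Its defaults *are* the study conditions the
package targets: 17 reference subjects, 131 patients, ~200,000 reads
per sample, generative hazard ratios 3.24 (aneuploidy) and 2.92
(CTC ≥ 5), and censoring tuned to roughly 70% observed deaths.

* **Arm weights** are proportional to arm length from the cytoband
  table — a proxy for true LINE-1 density (no LINE-1 map is shipped).
  This preserves the rank structure the normalization needs to be
  exercised, nothing more.
* **Count noise** is Dirichlet-multinomial with a single dispersion
  parameter (default $2\times10^{-5}$, about 3% CV on a typical arm
  fraction — the scale of amplicon-assay variability between healthy
  subjects); dispersion 0 gives a pure multinomial, and a
  `deterministic` mode emits rounded expected counts for exact tests.
  The published method states no noise model for healthy-panel
  variability; this choice is ours and is flagged as such.
* **Tumour fractions** follow a point mass at 0 (probability 0.35,
  mimicking cohorts with undetectable ctDNA) mixed with a
  Beta(1.2, 3.5) on (0, 1].
* **Copy-number profiles** alter each arm independently (25% per arm;
  gains to copy 3–4 with probability 0.6, single-copy losses otherwise)
  — a caricature of CRPC genomes that produces realistic multi-arm
  signal without encoding any specific published profile.
* **CTC counts** are negative binomial with log-mean linear in tumour
  fraction (intercept $\log 2$, slope 6, size 0.8): over-dispersed
  non-negative integers whose association with the score emerges only
  through the shared tumour fraction.
* **Survival** is exponential with hazard
  $\lambda_0 \exp(\beta_A \mathbb{1}[\text{aneuploid}] + \beta_C
  \mathbb{1}[\text{CTC} \ge 5])$, $\lambda_0 = 0.02$/month, and
  independent exponential censoring at 0.02/month. Proportional hazards
  holds by construction, so Cox recovery is a valid parameter-recovery
  oracle. The true aneuploidy label is "non-zero tumour fraction and a
  non-diploid profile".

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: GC and amplification biases, the true
LINE-1 arm-weight spectrum, clonal heterogeneity and subclonal copy
number, informative censoring, correlated missingness in labs, and any
association of WHO status or labs with outcome (they are drawn
independent of hazard, so the univariate screen's behaviour on them is
purely its type-I behaviour).

## Numerical and testing choices

* Panel SD uses $n-1$; a panel with any zero per-arm SD is rejected as
  degenerate rather than patched.
* Threshold comparisons are inclusive ($\ge$) everywhere.
* All tabular output is TSV with floats at 10 significant digits so
  data-driven thresholds round-trip exactly; summaries are JSON.
* The test suite's problem sizes are chosen to make the statistical
  assertions sharp but quick: 200 replicates at $n = 500$ for hazard-
  ratio recovery (mean fitted log-HR within 3 Monte-Carlo SEs of truth),
  2,000 null cohorts at $n = 131$ for the screen's 10% ± 2% retention
  calibration, 100 random instances for cutpoint-vs-exhaustive-scan
  equivalence, and toy ≤ 5-arm panels with hand-computed oracles at
  $10^{-9}$ for the scoring arithmetic.
* The shipped cytoband table uses real hg19 chromosome lengths and
  standard centromere boundaries but synthetic intra-arm banding (it is
  named accordingly); arm boundaries and the 48/42 arm accounting match
  the real file, which is all the pipeline consumes.

## Known limitations

The package scores relative arm imbalance; it does not estimate an
absolute tumour-fraction percentage, call segment-level copy number, or
model within-arm events. The cutpoint procedure ignores follow-up time
by design. Cox models assume proportional hazards and no time-dependent
covariates; no proportionality diagnostics are included. Real-data
behaviour of the ≥ 5 call depends on the reference panel matching the
assay batch — panel transfer across protocols is out of scope.
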