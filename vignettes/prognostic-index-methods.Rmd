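---
title: "Methods: genotype-score prognostic indices for survival cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-score prognostic indices for survival cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snpindex)
```

## Scope and model

`snpindex` analyzes cohorts of surgically treated cancer patients — the
motivating setting is early-stage non-small cell lung cancer — genotyped
on a small panel of biallelic germline SNPs, with two right-censored
endpoints per subject: overall survival (OS, surgery to death from any
cause) and disease-free survival (DFS, surgery to recurrence or death,
whichever first). Three analysis layers build on each other:

1. **Per-SNP association.** For each SNP the three genotypes are
   collapsed under a genetic model — additive (risk-allele count 0/1/2),
   dominant (carrier indicator) or recessive (risk-homozygote
   indicator) — and entered into a Cox proportional-hazards model
   together with the clinical adjustment covariates. Genotype-level
   contrasts (heterozygote and variant homozygote, each against the wild
   homozygote) are fitted alongside the three collapsed models.
   Descriptive genetics (genotype counts with column percentages, minor
   allele frequency, a one-degree-of-freedom Hardy-Weinberg chi-square)
   and Kaplan-Meier 5-year rates per genotype round out the layer.
2. **Scoring.** Each genotype receives a score: 1/2/3 by risk-allele
   count under the additive model, 1 or 3 under the two-level models,
   with higher score meaning worse expected prognosis. The per-subject
   prognostic index is the sum over the panel; for the default
   eight-SNP panel (three additive, five two-level) the achievable range
   is 8 to 24.
3. **Risk groups.** An integer cutoff splits subjects into low
   (index < cutoff) and high (index ≥ cutoff) risk groups, compared by
   Kaplan-Meier curves, the log-rank test and an adjusted Cox model with
   the high-risk indicator.

The assumptions are the standard ones of this design: proportional
hazards for all fitted effects, non-informative censoring, genotypes
missing completely at random, and independence of subjects.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `covariate_set` | `"table2"` | Adjustment set: age group, sex, smoking status, histology, pathologic stage. Preset `"methods"` adds adjuvant chemotherapy. |
| `cutoff` | `"auto"` | Approximate-tertile integer cutoff; an integer (e.g. 15) reproduces a fixed published threshold. |
| `target_fraction` | 1/3 | High-risk fraction targeted by the automatic cutoff. |
| `ties` | `"efron"` | Tie handling in all Cox fits; `"breslow"` available for cross-checks. |
| `horizon` | 60 months | Reporting horizon for "5-year" Kaplan-Meier rates. |
| `missing_token` | `"NA"` | Cohort-file marker for a failed genotype call. |

Times are in months throughout; "5-year" means 60 months. Cohort files
never state a unit, so the convention is fixed here once: month
resolution is how such surgical cohorts are typically recorded, and it
produces the heavy event-time ties that motivated the Efron default (the
Efron approximation is the more accurate partial-likelihood correction
when many subjects share event times; Breslow is retained behind a
switch because legacy statistical suites differ in their default).

Age enters the models as the binary ≤64 / >64 years split rather than
continuously: the data model stores the dichotomy because adjusted
analyses in this design are reported, and therefore reproducible, from
categorical covariates only. Reference levels are fixed and documented:
age ≤64, female, never-smoker, squamous-cell histology, stage I, no
adjuvant chemotherapy.

## Design choices in the open parts of the procedure

**Model selection per SNP.** When the panel does not fix a SNP's genetic
model, the package selects the collapsed model with the smallest OS Wald
p-value among the converged candidates, breaking full-precision ties by
the order additive > recessive > dominant. OS rather than DFS drives
selection because the scores express relative risk of death. The
additive-first tie-break reflects that the additive model is the least
parameterized description when two collapsings explain the data equally
well.

**Risk orientation.** Scoring needs to know which allele is deleterious.
An explicit `risk_direction` in the panel wins; otherwise the sign of
the selected model's coefficient decides (positive: variant allele is
the risk allele). A exactly-zero coefficient with no declared
orientation is refused rather than guessed.

**Cutoff rule.** "Highest approximate tertile" is made precise as: the
integer c minimizing |Pr(index ≥ c) − 1/3| over the observed index
range, ties to the smaller c. On a discrete index an exact tertile is
generally unachievable; the scan is exhaustive, so the chosen cutoff is
within one subject's mass of the optimum by construction. In the
degenerate case of a constant index the rule returns an empty high
group (the distance to 1/3 is then 1/3, versus 2/3 for the all-high
split), and the downstream analysis refuses the single-group
classification explicitly.

**Missing genotypes.** Per-SNP analyses are complete-case with their own
denominators (each SNP keeps every subject genotyped for *it*); the
combined index is undefined for any subject missing any panel genotype,
and such subjects are absent from risk-group denominators. No
imputation, and no "score missing as low risk" shortcut: both would
silently shift the index distribution.

**p-values.** All tests are two-sided; no multiple-testing correction is
applied across the panel, matching the exploratory character of this
design. Users scanning many candidate SNPs should adjust externally.

## The synthetic-cohort generator

The generator exists so the pipeline can be exercised, calibrated and
power-analyzed without access to patient-level data, which for the
motivating study design are not publicly deposited. Its default
configuration emulates the statistical structure of an 814-subject
resected-NSCLC cohort:

- **Genotypes**: independent per-SNP Hardy-Weinberg draws at
  variant-allele frequencies back-calculated from the published genotype
  counts of the default panel (e.g. 0.141 for C3 rs2287845, 0.506 for
  CD3EAP rs967591). Per-SNP genotyping-failure rates (5–10 per 814)
  reproduce the varying per-SNP denominators of such studies.
- **Covariates**: independent Bernoulli/multinomial draws at the
  study-level prevalences (47% over 64 years, 73% male, 69%
  ever-smokers, histology SCC/AC/LCC ≈ 45/51/4%, 40% stage II–IIIA, 30%
  adjuvant chemotherapy).
- **Event times**: exponential baseline hazards for death and for
  recurrence, each scaled by exp(linear predictor). Genotype effects
  enter on the collapsed coding of each SNP's assigned model at the
  published adjusted hazard ratios (log scale), so the analysis model is
  correctly specified under the defaults; a genotype-level effect mode
  exists for misspecification experiments. Covariate effects are set to
  plausible magnitudes consistent with the published univariate 5-year
  rates (e.g. log 1.9 for stage II–IIIA on death).
- **Censoring**: administrative only — cutoff 90 months minus a uniform
  accrual offset over 80 months — the simplest mechanism for a surgical
  cohort with follow-up truncation; no dropout hazard.
- **Calibration**: with the above fixed, the two baseline rates
  (0.00102 and 0.00249 events per month) and the censoring window were
  chosen so the default cohort reproduces the study-level margins —
  30.1% deaths, 49.4% DFS events, Kaplan-Meier 5-year OS near 64% —
  which the test suite verifies over 50 seeds.

Death and recurrence are independent latent times given covariates (no
shared frailty): the emulated study reports no dependence structure, and
the DFS endpoint only needs their minimum. Observed times are rounded up
to whole months; DFS ≤ OS and "death implies DFS event" hold by
construction.

What the generator does **not** emulate: linkage disequilibrium between
panel SNPs (the default panel spans different genes), correlation
between covariates (e.g. sex and smoking, which are strongly associated
in real lung-cancer cohorts), informative censoring, competing risks,
and center effects. Passing recovery and calibration tests therefore
shows that the estimators are correct under the stated generative model
— not that the published cohort-specific estimates would reproduce on
real data, where these unmodeled features matter.

A master seed drives per-component substreams (one per SNP's genotype
draw, one for covariates, one for survival, one per SNP's missingness
mask), each derived deterministically from the seed and a component
label; adding a SNP to the panel therefore leaves all other draws
untouched, and a cohort is bit-reproducible from its seed.

## Numerical choices

- Cox fitting uses damped Newton iteration on the Efron/Breslow partial
  likelihood (via the standard `survival` machinery) with convergence
  tolerance 10⁻⁹ and at most 50 iterations; the test suite checks the
  maximizer against a brute-force grid search of the exact partial
  likelihood (resolution 10⁻⁵) on small tied and untied instances.
- Constant covariate columns are rejected as non-identifiable before
  fitting; diverging coefficients (complete separation, or a genotype
  stratum with zero events) clear the `converged` flag and the affected
  contrast is reported as non-estimable rather than as a huge number.
- Confidence intervals are log-scale Wald intervals at the exact normal
  0.975 quantile; p-values are two-sided Wald (per coefficient) and
  chi-square upper tails (log-rank, Hardy-Weinberg, Pearson).
- Greenwood variances accompany every Kaplan-Meier estimate; the curve
  is evaluated as a right-continuous step function with last value
  carried forward.
- Rounding (percentages to one decimal, HRs to two, p-values to
  compact scientific notation below 0.001) happens only in the report
  writers; model objects keep full precision.

## Validation problem sizes

The package validates itself at sizes chosen to make Monte-Carlo error
small relative to the tolerances while keeping the default test run
fast: exhaustive enumeration of all 6561 genotype combinations for the
scoring bounds; 200–400 replicates of n = 2000 for parameter recovery
at the packaged effect sizes (group hazard ratios 2.21 and 1.58,
recessive per-SNP hazard ratio 1.68), asserted on the log-hazard scale
within two Monte-Carlo standard errors; 50 seeds of the n = 814 default
cohort for marginal calibration; and 500 null simulations for the size
of the log-rank and Wald tests and the coverage of the Wald intervals.

## Known limitations

- The index weights every SNP equally by rank scores 1/2/3; no
  effect-size weighting, training/validation split, or time-dependent
  discrimination analysis is provided — the package implements the
  two-group design faithfully, including its simplicity.
- Proportional hazards is assumed, not diagnosed (no Schoenfeld
  residual machinery); users with long follow-up should check
  externally.
- The exact Hardy-Weinberg test is not implemented; the chi-square
  version is appropriate for the common variants a prognostic panel
  would use, but not for very rare alleles.
- VCF/PLINK import is out of scope; cohorts arrive as delimited text
  with two-letter genotype strings.
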