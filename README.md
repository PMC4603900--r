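# snpindex

Genotype-score prognostic indices for survival cohorts genotyped on a
small panel of biallelic SNPs.

## The problem

After curative surgery for early-stage non-small cell lung cancer
(NSCLC), patients with the same pathologic stage still differ widely in
their risk of recurrence and death. One line of prognostic research
combines several germline polymorphisms — each individually associated
with survival after resection — into a single summed score, the
**prognostic index**, and stratifies patients into high- and low-risk
groups. `snpindex` implements that analysis end to end for
epidemiologists and biostatisticians working with cohort tables of
clinical covariates, overall-survival (OS) and disease-free-survival
(DFS) outcomes, and per-SNP genotype calls.

## The method

For each biallelic SNP with wild allele W and variant allele V, the three
genotypes WW / WV / VV are collapsed under a **genetic model**: additive
(count of risk alleles, 0/1/2), dominant (any risk allele) or recessive
(risk-allele homozygote). Each SNP's association with survival is
estimated by a multivariable Cox proportional-hazards model

&nbsp;&nbsp;&nbsp;&nbsp;h(t | z, x) = h₀(t) · exp(β·code(z) + γᵀx)

adjusted for age group, sex, smoking status, tumor histology and
pathologic stage (optionally adjuvant chemotherapy), with the Efron
approximation for tied event times. The genetic model per SNP is either
fixed in the panel specification or selected as the collapsed model with
the smallest OS Wald p-value (ties broken additive > recessive >
dominant).

Genotypes are then scored 1 (low risk), 2 (intermediate, additive model
only) or 3 (high risk); the **prognostic index** of a subject is the sum
of the eight scores (range 8–24 for a panel of 3 additive + 5 two-level
SNPs). An integer cutoff placing approximately the highest tertile in
the high-risk group (or a fixed published cutoff such as 15) defines the
risk groups, which are compared by Kaplan-Meier curves, the log-rank
test and an adjusted Cox model.

The package also ships a calibrated synthetic-cohort generator
(Hardy-Weinberg genotypes, study-level covariate prevalences,
proportional-hazards event times for death and recurrence,
uniform-accrual administrative censoring) used for validation, power
studies and parameter-recovery experiments.

## Worked example

```r
library(snpindex)

sim <- generate_cohort(default_generator_config(n = 814, seed = 42))
cohort <- sim$cohort
cohort
#> snp_cohort: 814 subjects, 8 SNPs
#>   deaths: 246 (30.2%), DFS events: 395 (48.5%)

fit <- prognostic_index(cohort)
fit
#> Eight-SNP-style prognostic index fit
#>   subjects: 814 (743 with defined index)
#>   index range: 8-18, cutoff: 14 (auto)
#>   OS: high vs low risk aHR 2.07 (1.59-2.71), p = 9.85e-08
#>   DFS: high vs low risk aHR 1.65 (1.33-2.05), p = 5.24e-06

fit$combined$os
#> Risk-group analysis (OS), cutoff 14: n = 743 (71 excluded)
#>   low  risk: 506 (68.1%), events 121 (23.9%), 60-month rate 70%
#>   high risk: 237 (31.9%), events 99 (41.8%), 60-month rate 50%
#>   log-rank p = 2.19e-08; adjusted HR 2.07 (1.59-2.71), p = 9.85e-08
```

Reading the output: 71 of 814 simulated subjects have at least one
failed genotype call, so their index is undefined and they are excluded
from the combined analysis (each per-SNP analysis keeps its own
complete-case denominator). The automatic cutoff 14 puts 31.9% of
subjects in the high-risk group — the closest achievable fraction to a
tertile on this integer-valued index — and the high-risk group dies at
roughly twice the adjusted hazard of the low-risk group (aHR 2.07),
with 5-year OS 50% vs 70%.

`summary(fit)` adds the per-SNP table (counts, MAF, Hardy-Weinberg p,
selected model, adjusted HR); `predict(fit, newdata)` scores new
subjects; `plot(fit, "os")` draws the risk-group Kaplan-Meier curves.
`run_pipeline()` writes the full set of report tables (univariate
clinical analysis, per-SNP association, combined analysis, KM curve
points, per-subject indices) plus a JSON manifest, and
`inst/scripts/snpindex.R` exposes `simulate` / `per-snp` / `index` /
`run` subcommands for shell use.

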