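---
title: "COXEN chemosensitivity prediction: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{COXEN chemosensitivity prediction: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoxenPredict)
```

## The scientific problem

Chemotherapy regimens for ER-negative breast cancer combine several
single agents (paclitaxel `T`, 5-fluorouracil `F`, doxorubicin `A`,
cyclophosphamide `C`), yet response biomarkers are usually developed for
the regimen as a whole. CoxenPredict implements the alternative
strategy of building one expression biomarker *per drug* from in vitro
cell-line screens and translating it to patients via COXEN —
COexpression ExtrapolatioN — without ever training on patient outcomes.

The pipeline has five stages:

1. **Association discovery.** Each gene's expression across cell lines
   is tested against the drug's GI50-style activity with one of five
   statistics: Pearson, Spearman, Welch *t* on a median-activity
   sensitive/resistant split, ANCOVA with tissue-of-origin as covariate,
   or rank-based ANCOVA. Genes are ranked by p-value and the top `topK`
   (default 500) become candidates.
2. **COXEN selection.** A candidate's COXEN score between the cell-line
   panel and a *patient reference cohort* is the correlation, across a
   reference gene set, of its two coexpression vectors — a "correlation
   of correlations". High scores mark genes whose coexpression context
   is preserved from cell lines to tumors. The `nSelect` highest-scoring
   candidates form the drug's biomarker set; the defaults `T = 33`,
   `F = 56`, `A = 27`, `C = 68` follow the reported optimal sizes for
   the four standard agents. The patient reference cohort is used *only*
   here; it is never scored or evaluated.
3. **Per-drug modeling.** Biomarker genes are standardized on the
   training cell lines, a PCA is taken of the standardized submatrix,
   and activity is regressed on the leading components (smallest number
   explaining ≥ 80% of variance, capped at 10). Training uses only
   cell-line data.
4. **Cohort scoring and combination.** Patient cohorts are scored by the
   same fixed linear rule, with genes re-standardized *within the
   cohort* by default (cell lines and tumors are different measurement
   systems; an option applies the stored training standardization
   instead). Raw scores become within-cohort rank percentiles,
   `(rank - 1) / (n - 1)` with midranks, and per-drug percentiles are
   combined either by a main-effects logistic regression on pCR
   (fit on a dedicated cohort, falling back to equal weights under
   complete separation) or by an unfitted equal-weight mean.
5. **Evaluation.** On a held-out validation cohort the combined score is
   summarized by the Mann–Whitney AUC against pCR/RD, the Wilcoxon
   rank-sum test, Kaplan–Meier curves and the log-rank test after
   dichotomizing at the top 30% ("COXEN-positive"), the NPV of the
   COXEN-negative group, and the joint false-negative risk of several
   independent single-drug predictors (the product of per-drug `1 - NPV`
   values; two drugs at 0.30 each give 0.09).

## The synthetic data generator

Because the original cohorts are external data sets, the package ships a
latent-factor generator whose defaults *are* the study conditions; every
validation property is computed on its output.

Cell-line expression for `nGenes` genes across `nCellLines` lines is
built from `kBg = 5` shared background factors (loadings `N(0, 1)`,
noise sd `0.7`); each drug additionally has a signature factor on which
its `nSignatureGenesPerDrug` planted genes load with `U(0.5, 0.9)`
weights. Rows are standardized to mean 0, sd 1. Drug activity is
`signatureEffect` times the summed signature expression, plus centered
tissue-of-origin offsets (`nTissues` levels spaced by `tissueShift`),
plus `N(0, 1)` noise.

Patient cohorts share the gene universe but are a *different system*:
the patient panels draw their own background loading structure once per
study, shared by all cohorts. Only the **concordant** fraction
(`concordantFraction`, default 0.5) of each drug's signature genes keeps
its cell-line signature loadings in patients; the rest lose them and
behave as background genes. This is exactly the structure COXEN is
meant to detect: concordant signature genes preserve their coexpression
context across systems, discordant ones do not, and background genes
have unrelated coexpression in the two systems.

Each patient's true susceptibility score is the mean standardized
signature projection over drugs. Observed outcomes follow
`pCR ~ Bernoulli(plogis(responseIntercept + responseSlope * score))` and
`time ~ Exponential(baselineHazard * exp(-hazardLogRatio * score))` with
independent exponential censoring at `censorRate`.

### Default parameters

| Parameter | Default | Rationale |
|---|---|---|
| `nCellLines` | 60 | NCI-60-sized screen |
| `nPatients` | 200 | neoadjuvant-cohort scale |
| `nGenes` | 1000 | desk-scale transcriptome |
| `nSignatureGenesPerDrug` | 20 | tens of genes per drug signature |
| `nDrugs` | 2 | two-drug combination (`T`, `F` by default) |
| `signatureEffect` | 0.6 | moderate in vitro signal |
| `concordantFraction` | 0.5 | half the signature survives translation |
| `nTissues`, `tissueShift` | 3, 0.5 | histology nuisance for ANCOVA |
| `responseIntercept` | −1 | baseline pCR rate ≈ 27%, matching 20–30% neoadjuvant rates |
| `responseSlope` | 2 | informative but noisy response channel |
| `baselineHazard` | 1/60 per month | median survival on the ~60-month scale |
| `hazardLogRatio` | 0.5 | score-dependent hazard |
| `censorRate` | 1/120 per month | roughly one-third censoring |
| `seed` | 1 | reproducibility root |

All per-cohort randomness is derived from the single seed via
`(seed + 7919 * offset) mod (2^31 - 1)` with a distinct offset per
cohort index, so identical configurations reproduce identical studies
byte for byte, and additional independent cohorts can be drawn from the
same ground truth by incrementing `cohortIndex`.

## Numerical and policy choices

* **Candidate ranking ties** are broken by smaller p-value, then larger
  |statistic|, then lexicographic gene ID; COXEN selection ties by
  higher score, then candidate rank, then gene ID. Selection is fully
  deterministic.
* **Welch split**: lines with activity strictly above the median are
  "sensitive"; median-valued lines fall in the resistant group.
* **Rank-sum test** uses the exact permutation distribution when the
  combined sample is below 20 with no ties, otherwise the normal
  approximation with midranks and continuity correction (the exact null
  is unavailable with ties).
* **Top-fraction dichotomization** always produces exactly
  `ceiling(fraction * n)` positives; boundary ties are resolved by
  deterministic sample-ID order (with a warning), keeping group sizes
  reproducible.
* **KM medians** are the earliest time the curve reaches 0.5; a curve
  that never does yields `NA`, to be read as "beyond max follow-up",
  which is reported alongside.
* **PC count**: smallest number of components reaching the variance
  threshold, capped at `maxComponents` and at the matrix rank; an
  explicit `nComponents` is truncated to the rank with a warning.
* **Logistic combination** detects complete separation (fitted
  probabilities at 0/1, non-convergence, or exploding coefficients) and
  falls back to equal weights with a warning rather than reporting an
  unstable fit.

## Validation design notes

The test suite recomputes oracles independently (brute-force AUC,
full-enumeration rank-sum, hand-tabulated log-rank) and checks null
calibration and signal recovery on the generator. Two design points
deserve explanation:

* *Dependence-aware uniformity testing.* Under the null
  (`signatureEffect = 0`) discovery p-values are marginally uniform, but
  genes share background factors, so p-values within one panel are
  dependent and a pooled Kolmogorov–Smirnov test over many panels is
  miscalibrated. The suite therefore tests marginal uniformity with
  quantile-wise t-statistics whose standard errors are clustered by seed
  (seeds are independent), plus a rejection-rate band at α = 0.05.
* *What "null" means end to end.* Silencing the activity channel
  (`signatureEffect = 0`) and the survival channel
  (`hazardLogRatio = 0`) does **not** make the pipeline's held-out AUC
  0.5, because the response channel (`responseSlope`) still links
  expression to pCR, and the logistic combination stage can learn that
  link from its fit cohort even when drug activity is pure noise —
  COXEN preferentially retains concordant signature genes whose
  coexpression is preserved regardless of activity. The genuine
  end-to-end null therefore also sets `responseSlope = 0`. This is worth
  knowing when interpreting real-data analyses: the combination-fit
  cohort is a supervised step, and any validation must be on a cohort
  untouched by both COXEN selection and combination fitting (the
  pipeline enforces the former and keeps the latter cohorts distinct).

## Limitations

* The generator is linear-Gaussian with exponential survival; it does
  not model batch effects, missingness patterns, platform differences
  beyond an affine per-system remap, or correlated censoring.
* The joint false-negative risk multiplies per-drug risks under an
  explicit independence assumption; correlated predictors would make the
  bound optimistic.
* Survival enters evaluation only; no survival-supervised training is
  provided, mirroring the in-vitro-only training design.
* The rank-based ANCOVA uses midranks and a normal-theory slope test; at
  very small panels its p-values are approximate.
* The equal-weight combination assumes comparably scaled percentiles per
  drug, which within-cohort rank-percentile conversion guarantees, but
  it cannot down-weight an uninformative drug.
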