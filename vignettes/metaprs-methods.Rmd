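---
title: "Methods: meta polygenic risk scores for type 2 diabetes prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: meta polygenic risk scores for type 2 diabetes prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaprs)
```

## The problem

Single-trait polygenic risk scores (PRS) for type 2 diabetes (T2D)
aggregate the effects of many common variants into one number per
person.  Because inflammation and lipid metabolism are mechanistically
entangled with T2D — particularly in people living with HIV, where
chronic immune activation and antiretroviral-associated dyslipidemia
raise T2D risk — a natural question is whether *combining* a T2D score
with scores for inflammatory markers (IL-1ra, IL-6, IL-8, TNF-R1, CRP)
or lipid traits (LDL-C, HDL-C, TG) improves prevalent-T2D prediction.
`metaprs` implements that whole analysis as a reusable, tested pipeline:
genotype QC and cross-platform harmonization, component-PRS computation
from PGS-Catalog-style scoring files, meta-score construction, and the
standard discrimination statistics — all exercisable on a bundled
synthetic-cohort generator, since the motivating cohorts are under
controlled access.

## The model

Each component score for individual $i$ is the usual weighted allele
count over the scoring file's variants,
$s_{ik} = \sum_j w_{jk}\, d^{*}_{ij}$, where $d^{*}_{ij}$ is the imputed
dosage after allele harmonization (see below).  Scores are standardized
to zero mean and unit SD, $Z_{ik}$, and the meta-score is the weighted
average

$$\mathrm{PRS}^{meta}_{i} \;=\; \frac{\sum_k \beta_k Z_{ik}}{\sum_k \beta_k},$$

with $\beta_k$ the per-trait log-odds from an elastic-net logistic
regression of T2D on the $Z$ columns, adjusted (unpenalized) for age,
age squared, sex and 10 principal components.  Two presets are packaged:
*meta-inflammation* (T2D + five inflammatory markers, $k = 6$) and
*meta-lipids* (T2D + three lipid traits, $k = 4$).  The elastic-net
mixing/penalty grid is searched by ten-fold cross-validated AUC with
outcome-stratified folds; all trait coefficients are reported, including
exact zeros at the selected penalty.

Prediction is evaluated with five nested logistic models: Model 1
(age, age², sex, 10 PCs, genotyping platform), Model 2 (Model 1 +
ART use, statin use, BMI, SBP, smoking), and Models 3–5 (Model 2 + the
single-trait T2D score, the meta-inflammation score, or the meta-lipids
score, each per SD).  Discrimination is summarized by the Mann–Whitney
AUC with DeLong structural-component variance, pairwise DeLong tests,
Nagelkerke pseudo-$R^2$ (with the "PRS $R^2$" defined as the full-model
$R^2$ minus the Model 2 $R^2$), and the category-free (continuous) net
reclassification improvement with a seeded percentile bootstrap.

## Tunable parameters that matter

| parameter | default | why |
|---|---|---|
| variant call rate min | 0.95 (cnics preset) | variants with >5% missingness removed first |
| MAF min | 0.01 | folded minor allele frequency from mean dosage / 2 |
| HWE exact p min | 1e-5 (cnics), 1e-12 (regards1) | plain exact conditional test, hard-called genotypes |
| sample call rate min | 0.90 | applied before relatedness |
| pi-hat max | 0.9 | flags duplicates/identity; lower-call-rate member removed |
| platform-association p | 5e-8 | genome-wide threshold for the harmonization filter |
| n PCs | 10 | EIGENSTRAT-style normalization, `2\hat p` centering, `sqrt(2\hat p(1-\hat p))` scaling |
| elastic-net mixing grid | 0.1, 0.25, 0.5, 0.75, 1 | the method is named, not the grid; 0 (ridge) accepted for diagnostics |
| CV folds | 10 | stratified by outcome, drawn once per fit from a fold seed |
| training fraction | 0.70 | simple random seeded split |
| NRI bootstrap | 1000 draws | percentile CI over individuals, seeded |

## Allele harmonization

Scoring records are matched to the panel by chromosome + position;
panel dosages count the `alt` allele.  A record whose effect allele is
the panel's `alt` contributes $w \cdot d$ (*direct*); effect equal to
`ref` contributes $w \cdot (2-d)$ (*allele_swap*); records matching only
after complementing both alleles are *strand_complement* (dosage
unchanged) or *complement_then_swap*.  A/T and C/G records are always
dropped — their strand cannot be resolved from alleles alone — as are
unmatched positions and irreconcilable allele pairs.  Missing dosages
are mean-imputed by $2\hat p$ (configurable to omit-and-renormalize).

## What the synthetic generator emulates — and what it does not

`sim_config()` / `simulate_cohort()` produce: independent variants with
allele frequencies in a configurable range, optionally differentiated
across two ancestry strata by a Balding–Nichols model; imputed-dosage
noise (clipped Gaussian around the allele count) and missingness;
strand-ambiguous variants at a configurable rate; nine sparse scoring
files written with deliberate allele-orientation swaps (weight negated,
preserving the underlying score up to a constant) and strand flips, to
exercise harmonization; a platform label and an optional batch artefact
(allele frequency shifted on the last platform for a chosen variant
fraction — injected *after* the outcome is drawn, so it is purely
technical); and a Bernoulli outcome from a logistic model
$\alpha + \sum_k \gamma_k Z^{*}_{ik} + \text{covariates}$, where
$Z^{*}$ are the true in-sample-standardized component scores, so each
$\gamma_k$ is a recoverable per-1-SD log-odds.  Continuous covariates
are centered (age at 50, BMI at 28, SBP at 127) before the stated
per-unit effects apply, so the intercept controls prevalence.

A logistic (rather than probit/liability) outcome model was chosen
deliberately: logistic regression on the validation cohort then
estimates exactly the generative per-SD log-odds, which is what the
parameter-recovery acceptance tests check.

Not emulated: linkage disequilibrium (variants are independent),
imputation quality scores, realistic relatedness structure (only
explicit duplicates), genotype-derived sex checks, and clinical
phenotype ascertainment (the binary outcome is generated directly).  A
green simulation test therefore establishes internal correctness of the
statistical machinery, not robustness to LD-induced weight correlation
or phenotype misclassification.

## Numerical choices and degenerate inputs

* **HWE test.** Plain exact conditional test (no mid-p): the p-value is
  the total probability of heterozygote counts no more probable than the
  one observed, under the classical conditional distribution given
  allele counts; computed on the log scale and normalized, exact against
  enumeration to 1e-12 for all tables with $n \le 200$.  Dosages are
  hard-called (rounded; entries more than 0.1 from an integer set
  missing) for HWE and pi-hat only, since both are defined on genotype
  counts.
* **Filter order.** Call rate → MAF → HWE → ambiguous → multi-allelic,
  fixed so every removed variant has a deterministic first-failing
  reason; monomorphic variants get HWE p = 1 and are removed by the MAF
  rule.  QC is idempotent.
* **Pi-hat.** PLINK-style method of moments from IBS counts with
  unbiased (falling-factorial) allele-frequency moments; the final
  estimate is clipped to [0, 1].  Identical genotype vectors give
  exactly 1.  At a 500-variant panel the per-pair Monte-Carlo SD is
  ~0.035, so the extreme over thousands of unrelated pairs routinely
  exceeds 0.1 — an information limit of the estimator at that panel
  size, which is why the tests bound the bulk of the distribution rather
  than its maximum, and why production use should estimate relatedness
  on as many variants as possible.
* **Platform filter.** Per variant, logistic regression of the platform
  indicator on dosage plus PCs (the paper leaves predictor-versus-
  covariate orientation ambiguous; dosage-as-predictor with PC
  adjustment is implemented); Wald p on the dosage coefficient; with
  more than two platforms the comparison proceeds by successive merges.
  Complete separation counts as removal with its own reason code.  Note
  that on small simulated panels a large contaminated fraction leaks
  into the PCs and mutes the test — at genome-wide scale the
  contaminated fraction is negligible, and the test fixtures mimic that
  by computing PCs on clean variants.
* **Meta-score denominators.** Negative component coefficients
  (plausible for HDL-C) are kept as-is in numerator and denominator; if
  the coefficients sum to zero the weighted average is undefined and the
  build errors, and a negative sum also errors rather than silently
  flipping the score's sign.
* **Standardization.** SD uses the $n-1$ convention everywhere;
  provenance (in-sample versus reference moments) is recorded on every
  standardized matrix.  Component scores are standardized *within* each
  evaluation cohort — "held fixed" is interpreted as applying to the
  meta-weights only, the stated open question — with reference-moment
  standardization available through `standardize_scores(reference=)`.
* **Quintiles.** Type-7 (linear interpolation) quantiles at
  20/40/60/80%; values equal to a cut point go to the lower bin, so tied
  blocks never straddle bins; the middle quintile is the reference level
  in the odds-ratio models.
* **AUC/DeLong.** Placement values via midranks (ties count ½); AUC CI
  is Wald on the AUC scale clipped to [0, 1] (no logit transform);
  identical prediction vectors short-circuit to p = 1 instead of 0/0.
* **NRI.** Category-free variant on fitted model probabilities; strict
  inequalities define up/down moves, ties contribute to neither; the
  event and non-event components always sum to the reported NRI.
  Model 2 is compared against Model 1, Models 3–5 against Model 2 (the
  comparison against Model 1 is also emitted).
* **Seeding.** One master simulation seed fans out into named,
  deterministically derived stage seeds (logged in the truth file);
  split, fold and bootstrap seeds are separate pipeline parameters, so
  the fitted meta-model is bit-identical across evaluation settings and
  an identical configuration reproduces byte-identical output tables.

## Known limitations

Independent-variant simulation cannot probe how correlated scoring
files behave under the elastic net; the 70/30 split is unstratified by
default (a `stratify` argument exists); survival/incident-disease
models, calibration metrics, PGS-Catalog downloads and genome-build
liftover are out of scope.  The NRI bootstrap coverage check in the
test suite runs at a reduced scale (150 replicates, n = 1500, 400
bootstrap draws) relative to the full-size study design (200 replicates,
n = 2000, 1000 draws) to stay inside the suite's runtime budget.

No empirical claim in this vignette goes beyond what the test suite
(`tests/testthat/`, in particular `test-acceptance.R`) computes.
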