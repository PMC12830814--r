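# metaprs

Meta polygenic risk scores for type 2 diabetes (T2D) risk prediction.

Polygenic risk scores (PRS) compress many small variant effects into one
per-person number.  Because inflammation and lipid metabolism are
biologically entangled with T2D — especially in people living with HIV —
a meta-score that averages a T2D PRS with inflammatory-marker or
lipid-trait PRS is a candidate improvement over the single-trait score.
`metaprs` implements that analysis end to end for epidemiologists and
statistical geneticists who want to run it on their own dosage data or
study its behaviour on simulated cohorts:

* **Synthetic cohorts** — seeded generator for imputed dosages (two
  ancestry strata, platform batch artefacts, strand-ambiguous variants),
  nine PGS-Catalog-style scoring files with deliberate allele swaps and
  strand flips, covariates, and a logistic outcome with known per-SD
  effects.
* **Genotype QC** — call rate, folded MAF, exact Hardy–Weinberg test,
  PLINK-style method-of-moments pi-hat, EIGENSTRAT-normalized principal
  components, and a cross-platform harmonization filter (per-variant
  logistic platform association, PC-adjusted, removal at p < 5e-8).
* **PRS engine** — PGS-Catalog scoring-file parsing, allele/strand
  harmonization, `score = sum(w * dosage)` with mean imputation, and
  standardization with recorded provenance.
* **metaPRS** — elastic-net logistic regression (glmnet) of the outcome
  on standardized component scores with unpenalized covariates, selected
  by ten-fold cross-validated AUC, and the meta-score

  `PRS_meta = (sum_k beta_k * Z_k) / (sum_k beta_k)`

  with packaged trait presets *meta-inflammation* (T2D, IL-1ra, IL-6,
  IL-8, TNF-R1, CRP) and *meta-lipids* (T2D, LDL-C, HDL-C, TG).
* **Evaluation** — per-quintile (Q3 reference) and per-SD odds ratios;
  five nested prediction models; AUC with DeLong variance and paired
  DeLong tests; Nagelkerke pseudo-R²; continuous net reclassification
  improvement with seeded percentile-bootstrap intervals.

## Worked example

```r
library(metaprs)

cfg <- sim_config(n_individuals = 2000, n_variants = 200,
                  trait_effects = c(0.4, rep(0.05, 8)),      # per-SD log-odds
                  covariate_effects = c(age = 0.03, bmi = 0.06, smoking = 0.3),
                  seed = 42)
res <- run_pipeline(pipeline_config(sim = cfg, n_boot = 200, n_pcs = 4,
  enet = enet_config(alpha_grid = c(0.5, 1), n_folds = 5, fold_seed = 1),
  out_dir = "run42"))

res$models$inflammation
#> metaprs_model (6 traits; alpha=1, lambda=0.00498, CV-AUC=0.571)
#>    T2D IL-1ra   IL-6   IL-8 TNF-R1    CRP
#> 0.2009 0.0000 0.0000 0.0000 0.0000 0.0000

res
#> pipeline_result in run42
#>   training n = 1400 ; validation n = 600
#>     model             score    auc auc_lo auc_hi r2_full r2_prs    nri ...
#> 1 Model 1              <NA> 0.6002 0.5459 0.6544  0.0306     NA     NA
#> 2 Model 2              <NA> 0.6368 0.5840 0.6895  0.0640     NA 0.3341
#> 3 Model 3           T2D-PRS 0.6532 0.6005 0.7058  0.0759 0.0119 0.1671
#> 4 Model 4 meta-inflammation 0.6532 0.6005 0.7058  0.0759 0.0119 0.1671
#> 5 Model 5       meta-lipids 0.6559 0.6034 0.7085  0.0787 0.0147 0.1366
```

Reading the output: the elastic net put all its weight on the T2D
component (the generator gave it per-SD log-odds 0.4 versus 0.05 for the
rest), so the meta-inflammation score collapses onto the single-trait
score and Models 3 and 4 coincide.  Adding the score to the clinical
model lifts the validation AUC from 0.637 to 0.653 and contributes a
PRS-specific Nagelkerke R² of ~1.2% — the same qualitative picture as in
cohort studies, where clinical covariates dominate and genetic scores
add a moderate increment.  The per-SD validation odds ratio for the T2D
score in this run is 1.28 (95% CI 1.04–1.57), consistent with the
generative exp(0.4) ≈ 1.49 at this sample size.

Artifacts written to `run42/`: QC reports (`qc_*.tsv`), frozen model
JSONs, the quintile/per-SD association table (`table2_validation.tsv`),
the discrimination table (`table3_validation.tsv` + `.json`), the
serialized configuration with all seeds, and a stage log.  Identical
configuration + seeds reproduce these files byte for byte.

A command-line wrapper covers the same stages
(`simulate | qc | score | train-meta | apply-meta | associate | evaluate | run`):

```sh
Rscript inst/cli/metaprs.R simulate --n 1000 --variants 500 --seed 1 --out cohort/
Rscript inst/cli/metaprs.R qc --dosages cohort/dosages.tsv --preset cnics --out qc/
```

## Documentation

The methods vignette (`vignettes/metaprs-methods.Rmd`) describes the
model, the harmonization rules, what the simulator does and does not
emulate, all numerical conventions (quantile definition, SD convention,
tie handling, degenerate-input behaviour), and known limitations.
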