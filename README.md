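# recoverlab

Most patients who present with a mild traumatic brain injury (GCS 13–15) and
a *normal* CT scan are sent home, yet a large fraction have not fully
recovered three months later (extended Glasgow Outcome Scale, GOSE < 8).
`recoverlab` implements the full statistical pipeline for asking whether two
kinds of add-on information improve the existing clinical prognostic models
for this population:

* **serum brain-injury biomarkers** — GFAP (ng/ml), S100B (µg/L) and
  NFL (pg/ml), sampled within 24 h of injury, entered on the log scale; and
* **diffusion tensor imaging (DTI)** — mean FA and MD of the 48 white
  matter tracts of the JHU ICBM-DTI-81 atlas, condensed into a single
  lasso-based **DTI score**.

The original study data are access-restricted, so the package ships a
synthetic cohort generator with the same statistical structure (quadratic
ageing trajectories per tract, location/scale scanner batch effects,
log-normal biomarkers tied to outcome and sampling window, realistic
missingness, and a logistic outcome model with effects concentrated in a
configurable set of tracts). Every stage of the analysis is therefore fully
testable end to end.

## The pipeline

1. **Harmonization** (`fit_combat()`, `apply_combat()`): parametric
   empirical-Bayes ComBat removes per-scanner location and scale effects
   from the 96 tract metrics while preserving the variance tied to age,
   age², sex, time since injury, GCS and MR-abnormality status.
2. **Age detrending** (`fit_trajectory()`, `detrend()`): quadratic normal
   ageing trajectories fitted to healthy controls (orthogonal polynomial
   basis with stored constants) re-express every patient at the reference
   age of 44: corrected value = *f* + [pred(44) − pred(age)].
3. **Multiple imputation** (`impute_cohort()`, `pool_rubin()`): chained
   equations (predictive mean matching, Bayesian logistic draws,
   multinomial sampling) produce *m* completed datasets; all downstream
   estimates are pooled by Rubin's rules with Barnard–Rubin degrees of
   freedom, on the logit scale for AUC-type metrics.
4. **DTI score** (`fit_dti_lasso()`, `dti_score()`): lasso logistic
   regression of incomplete recovery on the 96 z-scored, age-corrected
   tract metrics, with the penalty chosen by 10×10 repeated cross-validation
   (minimum mean binomial deviance). The score is the predicted odds of
   incomplete recovery from DTI alone; its log enters the clinical models
   as one extra covariate. `selection_frequencies()` ranks tracts by how
   often they are selected across the bootstrap × imputation grid.
5. **Reference models** (`model_specs()`, `build_design()`,
   `fit_logistic()`): the five published clinical models (UPFRONT-ED,
   UPFRONT-PLUS, HeadSMART, CENTER-ED, CENTER-PLUS) refit to the cohort,
   with and without biomarker or DTI add-ons; nested variants compared by
   a likelihood-ratio test pooled across imputations (Meng–Rubin).
6. **Internal validation** (`validate()`, `bootstrap_optimism()`):
   Harrell's bootstrap optimism correction — by default the entire
   pipeline, including the DTI-score lasso, is refit inside every resample
   — for AUC, Nagelkerke R², Cox calibration intercept/slope, sensitivity,
   specificity, PPV and NPV.
7. **Biomarker triage** (`choose_cutoff()`, `triage_table()`): per
   biomarker and sampling window (<12 h, 12–24 h), the concentration
   cutoff maximizing specificity subject to a minimum sensitivity (0.90),
   with the scan-triage consequences: avoided MRIs (true negatives),
   unnecessary MRIs (false positives), missed incomplete recoveries
   (false negatives) and number needed to scan.

## Worked example

```r
library(recoverlab)

run <- run_pipeline(
  sim = sim_config(seed = 42),     # 153 patients, 157 controls, 17 scanners
  specs = "CENTER-ED", m = 3, n_boot = 50,
  cv_folds = 5, cv_repeats = 1, n_boot_freq = 50
)
print(run)
```

The run simulates the cohort, harmonizes and detrends the tract metrics,
imputes, validates the CENTER-ED model with and without the DTI score, and
prints (abridged):

```
Internal validation: CENTER-ED  (50 bootstrap x 3 imputations)
        metric apparent optimism corrected   ci_lo  ci_hi
           auc    0.688    0.081     0.607   0.561  0.651
Internal validation: CENTER-ED + dti (50 bootstrap x 3 imputations)
           auc    0.909    0.130     0.779    0.718 0.830

Nested likelihood-ratio tests (with vs without DTI):
  CENTER-ED: D = 36.856 on (1, 6.1) df, p = 0.000829

Top tracts by selection frequency ( 150 runs ):
                           tract laterality   fa_freq   md_freq mean_freq
           Uncinate fasciculus R      right 0.9133333 1.0000000 0.9566667
  Superior cerebellar peduncle L       left 0.9200000 0.9666667 0.9433333
  Posterior thalamic radiation L       left 0.8533333 0.9400000 0.8966667
```

Reading the output: the clinical model alone discriminates weakly
(optimism-corrected AUC 0.61); adding the DTI score raises the corrected
AUC to 0.78 and the nested likelihood-ratio test is decisive; and the three
tracts that truly carry outcome effects in the generator occupy the top
three selection-frequency ranks. The triage table (also printed) shows, for
each biomarker and sampling window, the cutoff meeting the 0.90 sensitivity
floor and how many MRI scans it would have avoided.

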