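---
title: "Methods: prognostic modelling of recovery after CT-negative mild TBI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: prognostic modelling of recovery after CT-negative mild TBI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

After a mild traumatic brain injury (GCS 13–15) with a normal CT, roughly
one patient in three has not recovered completely three months later
(GOSE < 8). The analysis implemented here asks two questions on such a
cohort: do serum brain-injury biomarkers (GFAP, S100B, NFL) or diffusion
tensor imaging (DTI) tract metrics *add* prognostic value to the existing
clinical models, and can biomarkers triage patients toward the (expensive,
less accessible) MRI? `recoverlab` provides the complete pipeline plus a
synthetic cohort generator so that every stage can be exercised and tested
without the access-restricted patient data.

# The synthetic cohort generator

`sim_config()` encodes the study conditions the package emulates, and the
tests and acceptance script run at those conditions:

* **Cohort sizes.** 153 patients aged 20–70 (uniform; the restricted study
  reports a median of 44) imaged on 17 different 3 T scanners, 157 healthy
  controls aged 21–68, and — for biomarker-cohort analyses — 1025 patients
  with a marginal incomplete-recovery prevalence of 0.38.
* **Tract metrics.** Each of the 48 JHU ICBM-DTI-81 tracts has a quadratic
  ageing trajectory for FA (declining with age) and MD (rising), with
  intercepts staggered across tracts. A subject's *biological deviation*
  from the trajectory is Gaussian (SD 0.02 FA, 0.025 MD in 10⁻³ mm²/s);
  the *observed* value adds a per-scanner additive shift and multiplies
  the deviation by a per-scanner scale factor — exactly the location/scale
  model ComBat assumes, which makes harmonization well-specified and its
  removal testable.
* **Outcome.** Incomplete recovery is drawn from a logistic model whose
  linear predictor sums the z-scored *true* (pre-batch, age-detrended)
  deviations of the effect tracts plus modest clinical effects (age, GCS,
  symptom burden, two-week psychological scores). The intercept is
  calibrated by root-finding so the marginal prevalence matches the
  configured value. The default effect tracts are the left superior
  cerebellar peduncle, right uncinate fasciculus and left posterior
  thalamic radiation — the three tracts reported as most prognostic — each
  acting through FA (−0.7 log-odds per SD) and MD (+0.7). The magnitude
  was calibrated once so that a DTI-only model reaches an AUC of about
  0.8, the published order of discrimination, and is not revisited.
* **Biomarkers.** Log-normal, with location depending on outcome group and
  sampling window: GFAP and S100B decay after the first 12 h, NFL rises;
  incomplete recovery shifts every distribution upward. Given outcome, the
  biomarkers are independent of the tract metrics — the joint law linking
  the two is not reported anywhere, so the generator deliberately does not
  invent one.
* **Missingness.** Missing at random given the always-observed age and
  GCS; two-week questionnaires (anxiety, depression, PTSD) default to
  ~26–27 % missing against 2–12 % for acute variables, mirroring the
  reported pattern, so imputation is exercised realistically. An MNAR
  switch (dependence on the unobserved value itself) exists for stress
  testing and is off by default.

What the generator does *not* emulate: raw diffusion images and their
processing, spatial correlation between neighbouring tracts, kinetic decay
of biomarkers within a window, ordinal GOSE dynamics, or any systematic
(non-random) missingness beyond the MNAR switch. Tests passing on this
generator therefore certify the statistical machinery, not image
processing, and real data with correlated tracts or informative
missingness may behave differently.

# Harmonization (ComBat)

`fit_combat()` implements the parametric empirical-Bayes location/scale
estimator: per-feature standardization by a pooled covariate regression
(residual variance with the 1/n divisor), method-of-moments normal and
inverse-gamma priors for per-batch location and scale, and iterated
conditional posterior means with a relative-change stopping rule of 1e-4 —
the same iteration the standard reference implementation uses, which is why
the two agree to ~1e-7 on shared fixtures. Covariates whose biological
variance must survive are age, age², sex, time since injury, GCS (15 for
controls) and the MR-abnormality flag; age² enters as a raw squared column
because only the column span matters here. Design choices: features with
zero variance are skipped with a warning (the scale posterior is undefined);
a singleton batch and a rank-deficient covariate design are errors naming
the culprit; applying a model to an unseen batch label is an error rather
than a silent pass-through. Patients and controls are harmonized *jointly*
before trajectories are fitted — whether the original analysis did this is
unstated, and joint fitting is the variant that keeps the two groups on one
scale.

A property worth knowing: empirical-Bayes shrinkage leaves a residual
per-feature batch mean difference of order w·√(2/n_batch) (w ≈ 1/3 when the
true shifts are homogeneous across features), so the *average* standardized
batch difference vanishes with cohort size while the *maximum* across 96
features stays a few times larger. The acceptance check therefore measures
the average on a 10,000-subject two-scanner cohort.

# Age detrending

Quadratic trajectories are fitted to harmonized controls per tract metric,
on a centred-and-normalized orthogonal polynomial basis whose constants are
stored in the model — predictions on new subjects are then exactly those of
the raw-polynomial fit, while the solve stays well conditioned. A patient
with observed value *f* at age *a* is re-expressed at the reference age 44
(configurable) as *f* + [pred(44) − pred(a)]; patients at the reference age
are untouched, the map is affine in *f*, and ages outside the fitted control
range are corrected anyway but flagged in an audit attribute, since
quadratic extrapolation is the caller's risk.

# Multiple imputation and pooling

`mice`-style chained equations are implemented in-package: initialization by
draws from observed margins, then 10 cycles over the incomplete variables in
increasing-missingness order. Methods per type: type-1 predictive mean
matching with 5 donors (continuous and ordinal variables), Bayesian logistic
draws (binary), and sampling from one-vs-rest logistic class scores
(unordered categorical). All other analysis variables act as predictors;
the outcome participates via GOSE, and the binary outcome flag is always
recomputed as GOSE < 8, so the defining invariant holds in every completed
dataset. Ten imputations are the study default; several tests and the
acceptance script scale down to m = 3 (and m = 2 inside the
selection-frequency grid) to keep a full run in minutes on one core — the
pooling formulas are identical at any m.

Rubin's rules (`pool_rubin()`) combine per-imputation estimates with
within-variance W, between-variance B, total T = W + (1 + 1/m)B and
Barnard–Rubin degrees of freedom (floored at 1 so the t quantile stays
defined when W ≈ 0). Boundary-respecting scales: logit for AUC and the
classification metrics, log for the calibration slope, identity otherwise;
the identity scale is used automatically whenever a value leaves the
transform's domain. Nested models are compared with the Meng–Rubin (D3)
pooled likelihood-ratio test, which reduces to the classical χ² test at
m = 1; the test needs the published m = 10 to have its nominal power —
at m = 3 the between-imputation correction is estimated from two degrees
of freedom and the test is conservative.

# The DTI score

Lasso logistic regression on the 96 age-corrected tract metrics, z-scored
with means/SDs of the fitting sample only (stored in the model, so applying
it to new subjects or to the fitting sample itself is exact). The penalty
grid has 100 log-spaced values from the smallest all-zero penalty λ_max down
to 1e-4·λ_max; λ is chosen to minimize mean binomial deviance over repeated
cross-validation — 10 folds × 10 repeats by default, read from the study's
"10 × 10" description; the minimum rule, not the 1-SE rule, matching
"minimize the mean prediction error". The score reported for a subject is
the *odds* of incomplete recovery from DTI alone; the *log*-odds is what
enters downstream logistic models (scale-stable under refitting; the choice
between odds and log-odds is not documented anywhere, so both are exposed).
A caveat established empirically in the tests: the deviance-minimizing λ
retains a tail of noise predictors (roughly 5–30 of 94 nulls at n = 400)
alongside every informative one — inherent λ-min behaviour, which is why
tract *selection frequency* across resamples, not a single fit's support,
is the ranking instrument.

# Internal validation

Harrell's optimism bootstrap, stratified on outcome (plain resampling by
flag), within each imputed dataset: refit the whole pipeline on the
resample, evaluate on the resample (boot-apparent) and on the original data
(test); optimism is the mean difference and corrected = apparent − optimism.
The single most consequential ambiguity in the source analysis is whether
the DTI-score lasso was refit inside each resample; `validation_config()`
defaults to the honest refit and exposes `refit_dti = FALSE` for the
cheaper fixed-score variant. The two differ materially: on synthetic data
the honest variant's corrected AUC is lower (and its corrected Nagelkerke
R² much lower — overconfident resample models are heavily penalized on
log-likelihood metrics), while the fixed-score variant reproduces the
published pattern of high corrected R². The acceptance script reports both.

Numerical guards, all visible in the output rather than silent: evaluation
probabilities are clamped to [1e-10, 1 − 1e-10] for likelihoods; test-data
Nagelkerke R² is truncated at −100 % (the conventional reporting floor);
recalibration intercept/slope are computed on probabilities clamped to
[0.001, 0.999] and reported as undefined for a resample when the estimate
exceeds ±20 (a flat, separation-induced likelihood); single-class resamples
are redrawn with a counter; a metric undefined in more than half the
resamples is flagged unstable. Classification metrics use a threshold equal
to the training-sample prevalence by default — the published tables do not
state their threshold, and the prevalence keeps sensitivity/specificity
away from degenerate corners; it is a configuration knob.

# Reference models and triage

The five clinical model specifications encode the published variable lists
with the documented substitutions: prior mental health problems replace
prior depression, neck pain and coping styles are omitted, pupils are
omitted, and HeadSMART's positive-CT indicator is auto-pruned as constant
in an all-normal-CT cohort. Education enters the UPFRONT models as a 1–3
score and its interaction with age as the numeric product. Biomarkers enter
on the log scale.

Cutoff selection scans midpoints of sorted unique concentrations plus
extremes; among cutoffs with sensitivity ≥ the floor (0.90 primary; 1.00,
0.95, 0.80 as sweeps) it returns the highest-specificity one, ties broken
toward the higher cutoff, with positivity defined as concentration ≥ cutoff
(strict inequality is a flag). Triage metrics are resubstitution estimates
— the analysis is exploratory and no optimism correction is applied. The
number needed to scan is defined here as (TP+FP)/TP, scans performed per
incomplete-recovery patient scanned; reconstructing the published table's
counts gives 2.18 where it prints 2.1, so the printed column evidently
follows a slightly different convention and ours is documented instead.
Display percentages are count/N rounded half-up.

# Problem sizes used in the shipped checks

The test suite and acceptance script run the pipeline at the study's
cohort sizes (153/157/17 scanners) but scale the resampling grids: 50
bootstrap resamples × 3 imputations for validation (from 200 × 10), 100
lasso runs for selection frequencies (from 2000), and 5-fold
single-repeat cross-validation inside resampled lasso fits (from 10 × 10).
These sizes keep a complete run in minutes on one core; the estimators are
identical at full scale, only Monte-Carlo error changes. Two consequences
of the scaled-down grids are documented in the tests themselves: selection
frequency ranks at 100 runs retain appreciable Monte-Carlo noise, and a
cohort of 153 occasionally contains a noise tract whose realized outcome
correlation rivals a true effect tract.

# Known limitations

* Tract metrics are generated independently across tracts; real tract
  atlases are spatially correlated, which would slow lasso selection-
  frequency convergence further.
* The honest-refit optimism correction is itself slightly biased for
  unstable selection pipelines (corrected AUC can dip below 0.5 on pure
  noise when the full-data lasso selects nothing but resample fits do).
* No MNAR sensitivity analysis beyond best/worst-case outcome imputation.
* No external validation or transport analysis; no ordinal GOSE modelling.
* Non-parametric ComBat, longitudinal ComBat and site-level nesting are
  out of scope; so are sex-specific or spline ageing trajectories.
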