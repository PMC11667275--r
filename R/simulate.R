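#' Default quadratic ageing trajectories for the 48 tracts
#'
#' FA declines (increasingly fast with age) and MD rises through adult life;
#' intercepts are staggered across tracts so tracts are distinguishable.
#' Coefficients are for a raw polynomial `b0 + b1*age + b2*age^2`, FA in
#' native units, MD in 1e-3 mm^2/s.
#'
#' @return list with 48 x 3 coefficient matrices `fa` and `md`
#'   (columns intercept, age, age^2; rownames are tract slugs).
#' @export
default_trajectories <- function() {
  atlas <- jhu_atlas()
  k <- seq_len(48L)
  fa <- cbind(
    intercept = 0.40 + 0.20 * (k - 1) / 47,
    age       = rep(4e-4, 48L),
    age2      = rep(-1e-5, 48L)
  )
  md <- cbind(
    intercept = 0.70 + 0.15 * (k - 1) / 47,
    age       = rep(-1e-3, 48L),
    age2      = rep(2e-5, 48L)
  )
  rownames(fa) <- rownames(md) <- atlas$slug
  list(fa = fa, md = md)
}

#' Default log-normal biomarker parameters
#'
#' Location/scale of the log-normal serum concentrations per biomarker,
#' outcome group and sampling window.
#' @return nested list `[[marker]][[group]][[window]]` of `c(meanlog, sdlog)`.
#' @export
default_biomarker_params <- function() {
  # meanlog/sdlog per biomarker x outcome group x sampling window.
  # Units: GFAP ng/ml, S100B ug/L, NFL pg/ml. GFAP and S100B decay after the
  # first 12 h; NFL rises. Incomplete recovery shifts every distribution up.
  mk <- function(ce, cl, ie, il, sd) list(
    complete   = list(early = c(meanlog = log(ce), sdlog = sd),
                      late  = c(meanlog = log(cl), sdlog = sd)),
    incomplete = list(early = c(meanlog = log(ie), sdlog = sd),
                      late  = c(meanlog = log(il), sdlog = sd))
  )
  list(
    gfap  = mk(0.10, 0.07, 0.25, 0.17, 1.0),
    s100b = mk(0.055, 0.045, 0.085, 0.065, 0.6),
    nfl   = mk(4.5, 7.0, 9.0, 16.0, 0.9)
  )
}

#' Default marginal missingness rates per cohort variable
#'
#' @return named numeric vector of probabilities.
#' @export
default_missing_rates <- function() {
  # Two-week questionnaires are much more often missing than acute variables.
  c(
    gose = 0.03,
    education_level = 0.10, prior_mental_health = 0.05, asa = 0.05,
    pta_ge_1h = 0.12, alcohol_intoxication = 0.08, injury_mechanism = 0.02,
    iss = 0.05, symptom_score = 0.10,
    headache = 0.08, concentration = 0.08, photophobia = 0.08,
    anxiety = 0.26, depression = 0.26, ptsd = 0.27,
    gfap = 0, s100b = 0, nfl = 0
  )
}

#' Default outcome-effect tract-metric pairs
#'
#' @return data.frame with columns `tract` and `metric`.
#' @export
default_effect_tracts <- function() {
  # The three tracts reported as most prognostic, each through FA and MD:
  # lower FA and higher MD raise the odds of incomplete recovery.
  data.frame(
    tract = rep(c("Superior cerebellar peduncle L",
                  "Uncinate fasciculus R",
                  "Posterior thalamic radiation L"), each = 2L),
    metric = rep(c("fa", "md"), 3L),
    stringsAsFactors = FALSE
  )
}

#' Configuration for the synthetic mTBI cohort generator
#'
#' Bundles every knob of the generator: cohort sizes, scanner batch structure,
#' ageing trajectories, which tract metrics carry outcome effects, biomarker
#' distributions, clinical effects and missingness. Defaults emulate the DTI
#' sub-study conditions: 153 patients aged 20-70 scanned on 17 different 3 T
#' machines, 157 controls aged 21-68, three prognostically dominant tracts,
#' and two-week questionnaires missing far more often than acute variables.
#'
#' @param n_patients,n_controls,n_scanners cohort sizes and number of scanner
#'   batches.
#' @param age_range,control_age_range age ranges (years), sampled uniformly.
#' @param trajectory_coeffs list of 48 x 3 raw-polynomial coefficient matrices
#'   `fa`, `md` (see [default_trajectories()]).
#' @param sigma residual (biological) SD per metric, `list(fa=, md=)`.
#' @param batch_shift additive scanner offsets, `list(fa=, md=)`, each length
#'   `n_scanners` (recycled from length 1).
#' @param batch_scale multiplicative residual-scale factor per scanner.
#' @param effect_tracts data.frame with columns `tract`, `metric` naming the
#'   tract-metric pairs whose z-scored true (pre-batch, age-detrended) values
#'   enter the outcome model.
#' @param effect_sizes log-odds per SD for each row of `effect_tracts`
#'   (recycled). Sign convention is applied by the caller; defaults are
#'   -0.7 for FA rows and +0.7 for MD rows.
#' @param clinical_effects named log-odds per SD (continuous) or per level
#'   (binary) for clinical covariates entering the outcome model.
#' @param biomarker_params nested list `[[marker]][[group]][[window]]` of
#'   `c(meanlog, sdlog)`; groups `complete`/`incomplete`, windows
#'   `early` (<12 h) / `late` (12-24 h).
#' @param missing_rates named marginal missingness probabilities.
#' @param mnar if `TRUE`, missingness additionally depends on the (possibly
#'   unobserved) value itself; off by default (missing at random).
#' @param prevalence marginal probability of incomplete recovery; the outcome
#'   model intercept is calibrated so the simulated prevalence matches it.
#' @param mr_abnormality_rate probability of a visible traumatic MR finding.
#' @param seed integer seed; every `simulate_*` call sets it, so repeated
#'   calls reproduce the same tables.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_patients = 153L,
                       n_controls = 157L,
                       n_scanners = 17L,
                       age_range = c(20, 70),
                       control_age_range = c(21, 68),
                       trajectory_coeffs = default_trajectories(),
                       sigma = list(fa = 0.02, md = 0.025),
                       batch_shift = NULL,
                       batch_scale = NULL,
                       effect_tracts = default_effect_tracts(),
                       effect_sizes = NULL,
                       clinical_effects = c(
                         age = 0.25, gcs = -0.25, symptom_score = 0.5,
                         iss = 0.2, prior_mental_health = 0.3,
                         headache = 0.3, concentration = 0.25,
                         photophobia = 0.2, anxiety = 0.3, depression = 0.25,
                         ptsd = 0.3
                       ),
                       biomarker_params = default_biomarker_params(),
                       missing_rates = default_missing_rates(),
                       mnar = FALSE,
                       prevalence = 0.38,
                       mr_abnormality_rate = 0.25,
                       seed = 1L) {
  if (n_scanners < 1L) stop("n_scanners must be >= 1")
  if (n_patients < 1L || n_controls < 0L) stop("cohort sizes must be positive")
  check_range <- function(r, what) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] >= r[2])
      stop("invalid ", what, ": must be finite c(lo, hi) with lo < hi")
  }
  check_range(age_range, "age_range")
  check_range(control_age_range, "control_age_range")
  if (sigma$fa < 0 || sigma$md < 0) stop("sigma must be non-negative")
  if (is.null(batch_shift))
    batch_shift <- list(
      fa = seq(-0.015, 0.015, length.out = n_scanners),
      md = seq(-0.02, 0.02, length.out = n_scanners)
    )
  batch_shift$fa <- rep_len(batch_shift$fa, n_scanners)
  batch_shift$md <- rep_len(batch_shift$md, n_scanners)
  if (is.null(batch_scale))
    batch_scale <- exp(seq(log(0.8), log(1.25), length.out = n_scanners))
  batch_scale <- rep_len(batch_scale, n_scanners)
  if (any(batch_scale <= 0)) stop("batch_scale factors must be positive")
  atlas <- jhu_atlas()
  if (nrow(effect_tracts)) {
    bad <- !(effect_tracts$tract %in% atlas$tract) |
      !(effect_tracts$metric %in% c("fa", "md"))
    if (any(bad))
      stop("unknown effect tract/metric: ",
           paste(effect_tracts$tract[bad], effect_tracts$metric[bad],
                 collapse = ", "))
  }
  if (is.null(effect_sizes))
    effect_sizes <- ifelse(effect_tracts$metric == "fa", -0.7, 0.7)
  effect_sizes <- rep_len(effect_sizes, nrow(effect_tracts))
  if (any(missing_rates < 0 | missing_rates > 1))
    stop("missing_rates must lie in [0, 1]")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie in (0, 1)")
  structure(list(
    n_patients = as.integer(n_patients), n_controls = as.integer(n_controls),
    n_scanners = as.integer(n_scanners),
    age_range = age_range, control_age_range = control_age_range,
    trajectory_coeffs = trajectory_coeffs, sigma = sigma,
    batch_shift = batch_shift, batch_scale = batch_scale,
    effect_tracts = effect_tracts, effect_sizes = effect_sizes,
    clinical_effects = clinical_effects,
    biomarker_params = biomarker_params,
    missing_rates = missing_rates, mnar = isTRUE(mnar),
    prevalence = prevalence, mr_abnormality_rate = mr_abnormality_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Evaluate the quadratic trajectories at given ages: n x 48 matrix per metric.
eval_trajectory <- function(coeffs, age) {
  X <- cbind(1, age, age^2)
  list(fa = X %*% t(coeffs$fa), md = X %*% t(coeffs$md))
}

# Draw the observed tract table given ages/scanners and return both the
# observed values and the latent biological deviations (pre-batch residuals).
draw_tracts <- function(config, age, scanner) {
  n <- length(age)
  atlas <- jhu_atlas()
  traj <- eval_trajectory(config$trajectory_coeffs, age)
  dev <- list(
    fa = matrix(stats::rnorm(n * 48L, 0, config$sigma$fa), n, 48L),
    md = matrix(stats::rnorm(n * 48L, 0, config$sigma$md), n, 48L)
  )
  scale <- config$batch_scale[scanner]
  obs <- list(
    fa = traj$fa + config$batch_shift$fa[scanner] + scale * dev$fa,
    md = traj$md + config$batch_shift$md[scanner] + scale * dev$md
  )
  for (m in c("fa", "md"))
    colnames(obs[[m]]) <- colnames(dev[[m]]) <- paste0(m, "_", atlas$slug)
  list(obs = obs, dev = dev)
}

#' Simulate the healthy control tract table
#'
#' Controls follow the configured quadratic age trajectories plus scanner
#' shift/scale batch effects and Gaussian residuals; none has a traumatic MR
#' abnormality.
#'
#' @param config a [sim_config()].
#' @return tract table data.frame: `subject_id`, `scanner_id`, `age`, `sex`,
#'   `days_since_injury` (0), `mr_abnormality` (FALSE), then 48 `fa_*` and 48
#'   `md_*` columns.
#' @export
simulate_controls <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_controls
  age <- stats::runif(n, config$control_age_range[1], config$control_age_range[2])
  scanner <- sample.int(config$n_scanners, n, replace = TRUE)
  dr <- draw_tracts(config, age, scanner)
  out <- data.frame(
    subject_id = sprintf("C%04d", seq_len(n)),
    scanner_id = paste0("scanner", scanner),
    age = age,
    sex = sample(c("M", "F"), n, replace = TRUE, prob = c(0.57, 0.43)),
    days_since_injury = 0,
    mr_abnormality = FALSE,
    stringsAsFactors = FALSE
  )
  cbind(out, as.data.frame(dr$obs$fa), as.data.frame(dr$obs$md))
}

#' Simulate the patient cohort: clinical table plus tract table
#'
#' Outcome (incomplete recovery, GOSE < 8) is drawn from a logistic model
#' whose linear predictor sums calibrated baseline log-odds, the configured
#' effects of z-scored true (pre-batch, age-detrended) tract values, and
#' clinical covariate effects. Biomarkers are log-normal with group- and
#' sampling-window-specific parameters, and missingness is applied missing at
#' random given age and GCS (always observed).
#'
#' @param config a [sim_config()].
#' @return list with `cohort` (clinical data.frame) and `tracts` (tract table
#'   as in [simulate_controls()]). The tract table carries the latent
#'   z-scored biological deviations as attribute `"true_z"` (patients x
#'   tract-metric matrix) for parameter-recovery checks.
#' @export
simulate_patients <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_patients
  age <- stats::runif(n, config$age_range[1], config$age_range[2])
  scanner <- sample.int(config$n_scanners, n, replace = TRUE)
  dr <- draw_tracts(config, age, scanner)

  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.64, 0.36))
  gcs <- sample(13:15, n, replace = TRUE, prob = c(0.05, 0.15, 0.80))
  cohort <- data.frame(
    subject_id = sprintf("P%04d", seq_len(n)),
    age = age,
    sex = sex,
    education_level = sample(1:3, n, replace = TRUE, prob = c(0.3, 0.4, 0.3)),
    prior_mental_health = stats::rbinom(n, 1, 0.25),
    asa = sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)),
    gcs = gcs,
    pta_ge_1h = stats::rbinom(n, 1, 0.3),
    alcohol_intoxication = stats::rbinom(n, 1, 0.2),
    injury_mechanism = sample(c("road_traffic", "fall", "violence", "other"),
                              n, replace = TRUE, prob = c(0.4, 0.4, 0.1, 0.1)),
    iss = pmin(1L + stats::rpois(n, 4), 25L),
    symptom_score = pmin(round(stats::rgamma(n, shape = 2, scale = 8)), 60L),
    headache = stats::rbinom(n, 1, 0.45),
    concentration = stats::rbinom(n, 1, 0.35),
    photophobia = stats::rbinom(n, 1, 0.25),
    anxiety = pmin(round(stats::rgamma(n, shape = 1.5, scale = 3)), 21L),
    depression = pmin(round(stats::rgamma(n, shape = 1.5, scale = 3.5)), 27L),
    ptsd = pmin(round(stats::rgamma(n, shape = 1.2, scale = 8)), 80L),
    stringsAsFactors = FALSE
  )

  # Linear predictor: z-scored true tract deviations for the effect tracts
  # plus clinical effects; intercept calibrated to the target prevalence.
  atlas <- jhu_atlas()
  lp <- numeric(n)
  et <- config$effect_tracts
  true_z <- cbind(dr$dev$fa / max(config$sigma$fa, .Machine$double.eps),
                  dr$dev$md / max(config$sigma$md, .Machine$double.eps))
  if (nrow(et)) {
    cols <- paste0(et$metric, "_", atlas$slug[match(et$tract, atlas$tract)])
    lp <- lp + as.vector(true_z[, cols, drop = FALSE] %*% config$effect_sizes)
  }
  zsc <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  ce <- config$clinical_effects
  for (v in names(ce)) lp <- lp + ce[[v]] * zsc(cohort[[v]])
  f <- function(b) mean(stats::plogis(b + lp)) - config$prevalence
  b0 <- stats::uniroot(f, c(-20, 20))$root
  outcome <- stats::rbinom(n, 1, stats::plogis(b0 + lp))
  cohort$gose <- ifelse(outcome == 1L, sample(3:7, n, replace = TRUE,
                                              prob = c(.05, .1, .2, .3, .35)), 8L)
  cohort$outcome <- as.integer(cohort$gose < 8L)

  # Biomarkers: log-normal given outcome group and sampling window.
  cohort$sample_time_h <- stats::runif(n, 1, 24)
  win <- ifelse(cohort$sample_time_h < 12, "early", "late")
  grp <- ifelse(outcome == 1L, "incomplete", "complete")
  for (bm in c("gfap", "s100b", "nfl")) {
    p <- config$biomarker_params[[bm]]
    ml <- mapply(function(g, w) p[[g]][[w]]["meanlog"], grp, win)
    sl <- mapply(function(g, w) p[[g]][[w]]["sdlog"], grp, win)
    cohort[[bm]] <- stats::rlnorm(n, ml, sl)
  }

  cohort <- apply_missingness(cohort, config)
  cohort$outcome <- ifelse(is.na(cohort$gose), NA_integer_,
                           as.integer(cohort$gose < 8L))

  tracts <- data.frame(
    subject_id = cohort$subject_id,
    scanner_id = paste0("scanner", scanner),
    age = age,
    sex = sex,
    days_since_injury = sample(0:31, n, replace = TRUE),
    mr_abnormality = stats::rbinom(n, 1, config$mr_abnormality_rate) == 1L,
    stringsAsFactors = FALSE
  )
  tracts <- cbind(tracts, as.data.frame(dr$obs$fa), as.data.frame(dr$obs$md))
  attr(tracts, "true_z") <- true_z
  list(cohort = cohort, tracts = tracts)
}

# Missing-at-random masking: the probability of a missing cell depends on the
# always-observed age and GCS; the MNAR switch adds dependence on the value.
apply_missingness <- function(cohort, config) {
  rates <- config$missing_rates
  n <- nrow(cohort)
  z_age <- as.vector(scale(cohort$age))
  z_gcs <- cohort$gcs - mean(cohort$gcs)
  driver <- 0.4 * z_age - 0.3 * z_gcs
  driver <- driver - mean(driver)
  for (v in names(rates)) {
    r <- rates[[v]]
    if (r <= 0 || !v %in% names(cohort)) next
    eta <- stats::qlogis(min(max(r, 1e-12), 1 - 1e-12)) + driver
    if (config$mnar) {
      zv <- suppressWarnings(as.numeric(cohort[[v]]))
      if (all(is.finite(zv))) eta <- eta + 0.5 * as.vector(scale(zv))
    }
    miss <- stats::rbinom(n, 1, stats::plogis(eta)) == 1L
    cohort[[v]][miss] <- NA
  }
  cohort
}
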