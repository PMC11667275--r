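#' Specification for a model using only the DTI score
#'
#' The "DTI only" column of the performance tables: a logistic model whose
#' sole predictor is the DTI covariate.
#'
#' @return a `model_spec` with no clinical predictors (use with
#'   `addon = "dti"`).
#' @export
dti_only_spec <- function() {
  structure(list(name = "DTI-only", predictors = character(0)),
            class = "model_spec")
}

#' Tract selection frequencies over the bootstrap-within-imputation grid
#'
#' Refits the DTI-score lasso on bootstrap resamples of each completed
#' dataset and aggregates how often each tract's FA/MD coefficient was
#' selected (the published analysis used 200 resamples in each of 10
#' imputations, i.e. 2000 runs).
#'
#' @param tractX age-corrected tract matrix (subjects x 96).
#' @param imputed `imputed_set` or list of completed data.frames with an
#'   `outcome` column.
#' @param n_boot resamples per imputation.
#' @param cv_folds,cv_repeats inner cross-validation specification.
#' @param seed integer seed.
#' @return list with `frequencies` (see [selection_frequencies()]) and
#'   `n_runs`.
#' @export
selection_frequency_run <- function(tractX, imputed, n_boot = 200L,
                                    cv_folds = 10L, cv_repeats = 10L,
                                    seed = 1L) {
  datasets <- if (inherits(imputed, "imputed_set")) imputed$datasets else imputed
  set.seed(seed)
  models <- list()
  for (i in seq_along(datasets)) {
    y <- datasets[[i]]$outcome
    n <- length(y)
    for (b in seq_len(n_boot)) {
      idx <- c(sample(which(y == 1), sum(y == 1), replace = TRUE),
               sample(which(y == 0), sum(y == 0), replace = TRUE))
      models[[length(models) + 1L]] <- fit_dti_lasso(
        tractX[idx, , drop = FALSE], y[idx],
        folds = cv_folds, repeats = cv_repeats,
        seed = seed + length(models)
      )
    }
  }
  list(frequencies = selection_frequencies(models), n_runs = length(models))
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Orchestrates the stages end to end: simulate controls and patients,
#' harmonize patients and controls jointly (ComBat), fit ageing trajectories
#' on the harmonized controls and detrend the patients to the reference age,
#' multiply impute the clinical data, internally validate each requested
#' model with and without the DTI score, compare nested models by the pooled
#' likelihood-ratio test, and run the biomarker triage analysis.
#'
#' @param sim a [sim_config()]; its seed drives every stage.
#' @param specs names of reference models to validate (see [model_specs()]).
#' @param m number of imputations.
#' @param n_boot bootstrap resamples per imputation.
#' @param cv_folds,cv_repeats cross-validation specification for the lasso.
#' @param n_boot_freq resamples per imputation for the selection-frequency
#'   table (0 skips it).
#' @param do_dti toggle the DTI stages (harmonize/detrend/score/validate with
#'   DTI); when off, a biomarker-only analysis still completes.
#' @param do_triage toggle the biomarker triage stage.
#' @param refit_dti honest (in-resample) lasso refitting, see
#'   [validation_config()].
#' @param out_dir optional directory: stage outputs are written as CSVs.
#' @return object of class `recoverlab_run` with the per-stage results and a
#'   manifest (sizes, seeds, wall times).
#' @export
run_pipeline <- function(sim = sim_config(), specs = "CENTER-ED",
                         m = 10L, n_boot = 200L,
                         cv_folds = 10L, cv_repeats = 10L,
                         n_boot_freq = 0L,
                         do_dti = TRUE, do_triage = TRUE,
                         refit_dti = TRUE, out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  manifest <- list(seed = sim$seed, stages = character(0), wall = list())
  tick <- function(stage) {
    manifest$stages <<- c(manifest$stages, stage)
    manifest$wall[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 2)
  }

  controls <- simulate_controls(sim)
  pats <- simulate_patients(sim)
  cohort <- pats$cohort
  tick("simulate")

  tractX <- NULL; combat <- NULL; trajectory <- NULL; detrended <- NULL
  if (do_dti) {
    joint <- rbind(controls, pats$tracts)
    combat <- fit_combat(joint, covariates = combat_covariates(joint, cohort))
    harmonized <- apply_combat(combat, joint,
                               covariates = combat_covariates(joint, cohort))
    h_controls <- harmonized[seq_len(nrow(controls)), , drop = FALSE]
    h_patients <- harmonized[-seq_len(nrow(controls)), , drop = FALSE]
    tick("harmonize")

    trajectory <- fit_trajectory(h_controls)
    detrended <- detrend(h_patients, trajectory)
    tc <- tract_columns()
    tractX <- as.matrix(detrended[, c(tc$fa, tc$md)])
    tick("detrend")
  }

  imputed <- impute_cohort(cohort, m = m, seed = sim$seed + 100L)
  tick("impute")

  addons <- if (do_dti) list(base = NULL, dti = "dti") else list(base = NULL)
  vcfg <- validation_config(n_boot = n_boot, seed = sim$seed + 200L,
                            refit_dti = refit_dti,
                            cv_folds = cv_folds, cv_repeats = cv_repeats)
  validations <- list()
  lrt <- list()
  for (s in specs) {
    for (a in names(addons)) {
      validations[[paste(s, a, sep = "/")]] <-
        validate(s, imputed, vcfg, addon = addons[[a]], tractX = tractX)
    }
    if (do_dti) {
      Xf <- Xr <- yl <- list()
      for (i in seq_len(m)) {
        dat <- imputed$datasets[[i]]
        dsm <- fit_dti_lasso(tractX, dat$outcome, folds = cv_folds,
                             repeats = cv_repeats, seed = sim$seed + 300L + i)
        dat$dti <- predict(dsm, tractX, type = "logodds")
        Xf[[i]] <- suppressWarnings(build_design(s, dat, addon = "dti"))
        Xr[[i]] <- suppressWarnings(build_design(s, dat))
        yl[[i]] <- dat$outcome
      }
      lrt[[s]] <- lrt_nested_mi(Xf, Xr, yl)
    }
  }
  if (do_dti) {
    validations[["DTI-only/dti"]] <-
      validate(dti_only_spec(), imputed, vcfg, addon = "dti", tractX = tractX)
  }
  tick("validate")

  freq <- NULL
  if (do_dti && n_boot_freq > 0L) {
    freq <- selection_frequency_run(tractX, imputed, n_boot = n_boot_freq,
                                    cv_folds = cv_folds,
                                    cv_repeats = cv_repeats,
                                    seed = sim$seed + 400L)
    tick("selection_frequencies")
  }

  triage <- NULL
  if (do_triage) {
    triage <- triage_table(cohort, min_sensitivity = 0.90,
                           sweep = c(1.00, 0.95, 0.80))
    tick("triage")
  }

  out <- structure(list(
    cohort = cohort, controls = controls, tracts = pats$tracts,
    combat = combat, trajectory = trajectory, detrended = detrended,
    tractX = tractX, imputed = imputed,
    validations = validations, lrt = lrt,
    selection = freq, triage = triage,
    manifest = manifest
  ), class = "recoverlab_run")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort(cohort, pats$tracts, out_dir)
    if (!is.null(detrended))
      write_full_precision(detrended, file.path(out_dir, "detrended.csv"))
    perf <- do.call(rbind, lapply(names(validations), function(k) {
      tb <- validations[[k]]$table
      cbind(model = k, tb)
    }))
    utils::write.csv(perf, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    if (!is.null(freq))
      utils::write.csv(freq$frequencies,
                       file.path(out_dir, "selection_frequencies.csv"),
                       row.names = FALSE)
    if (!is.null(triage)) {
      utils::write.csv(triage$table, file.path(out_dir, "triage.csv"),
                       row.names = FALSE)
      utils::write.csv(triage$sweep_table,
                       file.path(out_dir, "triage_sweep.csv"),
                       row.names = FALSE)
    }
  }
  out
}

#' @export
print.recoverlab_run <- function(x, ...) {
  cat("recoverlab pipeline run (seed", x$manifest$seed, ")\n")
  cat("  stages:", paste(x$manifest$stages, collapse = " -> "), "\n")
  cat("  patients:", nrow(x$cohort), "; controls:", nrow(x$controls),
      "; imputations:", x$imputed$m, "\n\n")
  run_report(x)
  invisible(x)
}

#' Human-readable summary of a pipeline run
#'
#' Prints the optimism-corrected performance table per model variant, the
#' nested-model likelihood-ratio tests, the top selected tracts (when
#' computed) and the biomarker triage table.
#'
#' @param run a `recoverlab_run`.
#' @return the run, invisibly.
#' @export
run_report <- function(run) {
  if (!length(run$validations)) {
    cat("(no validation results in this run)\n")
    return(invisible(run))
  }
  for (k in names(run$validations)) print(run$validations[[k]])
  if (length(run$lrt)) {
    cat("\nNested likelihood-ratio tests (with vs without DTI):\n")
    for (s in names(run$lrt)) {
      l <- run$lrt[[s]]
      cat(sprintf("  %s: D = %.3f on (%d, %.1f) df, p = %.3g\n",
                  s, l$statistic, l$df1, l$df2, l$p_value))
    }
  }
  if (!is.null(run$selection)) {
    cat("\nTop tracts by selection frequency (", run$selection$n_runs,
        "runs ):\n")
    print(utils::head(run$selection$frequencies, 8), row.names = FALSE)
  }
  if (!is.null(run$triage)) {
    cat("\nBiomarker triage (minimum sensitivity 0.90):\n")
    print(run$triage$table, row.names = FALSE)
  }
  invisible(run)
}
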