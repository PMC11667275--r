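#' Configuration for bootstrap-within-imputation internal validation
#'
#' @param n_boot bootstrap resamples per imputed dataset.
#' @param seed integer seed.
#' @param refit_dti if `TRUE` (honest validation, the default) the DTI-score
#'   lasso is refit inside every bootstrap resample; if `FALSE` the score is
#'   fixed once on the full data (cheaper, optimistically biased).
#' @param stratified resample subjects within outcome strata to reduce
#'   single-class resamples (plain resampling if `FALSE`).
#' @param threshold classification threshold for sensitivity/specificity/
#'   PPV/NPV; `NULL` uses the outcome prevalence of the training sample.
#' @param cv_folds,cv_repeats cross-validation specification for any lasso
#'   refit inside the loop.
#' @param max_redraws how often a single-class resample may be redrawn.
#' @param identity_resample degenerate diagnostic hook: every "resample" is
#'   the original data, so the optimism must be exactly zero.
#' @return object of class `validation_config`.
#' @export
validation_config <- function(n_boot = 200L, seed = 1L, refit_dti = TRUE,
                              stratified = TRUE, threshold = NULL,
                              cv_folds = 10L, cv_repeats = 10L,
                              max_redraws = 50L, identity_resample = FALSE) {
  stopifnot(n_boot >= 1L)
  structure(list(
    n_boot = as.integer(n_boot), seed = as.integer(seed),
    refit_dti = isTRUE(refit_dti), stratified = isTRUE(stratified),
    threshold = threshold, cv_folds = as.integer(cv_folds),
    cv_repeats = as.integer(cv_repeats), max_redraws = as.integer(max_redraws),
    identity_resample = isTRUE(identity_resample)
  ), class = "validation_config")
}

validation_metric_names <- function() {
  c("auc", "r2", "cal_intercept", "cal_slope",
    "sensitivity", "specificity", "ppv", "npv")
}

# All performance metrics of predictions p against outcomes y.
eval_metrics <- function(y, p, threshold) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  n <- length(y)
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  prev <- mean(y)
  ll0 <- n * (prev * log(prev) + (1 - prev) * log(1 - prev))
  r2 <- 100 * (1 - exp((2 / n) * (ll0 - ll))) / (1 - exp((2 / n) * ll0))
  # on evaluation data a badly wrong model can push R2 to arbitrarily large
  # negative values; truncate at -100%, the usual reporting convention
  r2 <- max(r2, -100)
  # recalibration parameters are computed on predictions clamped away from
  # 0/1: under (quasi-)separated resample fits the unbounded logits make the
  # intercept/slope estimates meaningless
  cal <- cox_calibration(y, pmin(pmax(p, 1e-3), 1 - 1e-3))
  # under (quasi-)separation the recalibration likelihood is flat and the
  # estimates wander; report them as undefined for this evaluation
  if (!is.finite(cal$intercept) || abs(cal$intercept) > 20)
    cal$intercept <- NA_real_
  if (!is.finite(cal$slope) || abs(cal$slope) > 20)
    cal$slope <- NA_real_
  cm <- classification_metrics(y, p, threshold)
  c(auc = auc(y, p), r2 = r2,
    cal_intercept = cal$intercept, cal_slope = cal$slope,
    sensitivity = cm$sensitivity, specificity = cm$specificity,
    ppv = cm$ppv, npv = cm$npv)
}

# Train the spec (+ add-ons, with optional in-loop lasso refit) on rows idx
# and return predictions on the training rows and on all rows.
train_predict <- function(idx, dat, y, spec, addon, tractX, config,
                          fixed_dti = NULL) {
  dat2 <- dat
  if ("dti" %in% addon) {
    if (config$refit_dti) {
      dsm <- fit_dti_lasso(tractX[idx, , drop = FALSE], y[idx],
                           folds = config$cv_folds,
                           repeats = config$cv_repeats,
                           seed = config$seed)
      dat2$dti <- predict(dsm, tractX, type = "logodds")
    } else {
      dat2$dti <- fixed_dti
    }
  }
  X <- suppressWarnings(build_design(spec, dat2, addon))
  fit <- suppressWarnings(fit_logistic(X[idx, , drop = FALSE], y[idx]))
  list(p_train = fit$fitted, p_all = predict(fit, X), fit = fit)
}

#' Bootstrap optimism of all model metrics on one completed dataset
#'
#' Harrell's procedure: for each bootstrap resample, the entire modelling
#' pipeline (including the DTI-score lasso when the model carries the DTI
#' covariate and the refit policy is on) is refit on the resample; each
#' metric is evaluated on the resample (boot-apparent) and on the original
#' data (test); optimism is the mean difference, and the corrected value is
#' the full-sample apparent value minus the optimism.
#'
#' @param dat one completed (no relevant missing values) clinical data.frame
#'   with an `outcome` column.
#' @param spec a `model_spec` or its name.
#' @param config a [validation_config()].
#' @param addon add-ons as in [build_design()].
#' @param tractX age-corrected tract-metric matrix aligned to `dat` rows
#'   (required for the `"dti"` add-on).
#' @return list with `apparent`, `optimism`, `corrected` (named metric
#'   vectors), `boot_test` (resamples x metrics matrix of test performance),
#'   `redraws` (single-class resamples redrawn), `unstable` (metrics
#'   undefined in more than half the resamples).
#' @export
bootstrap_optimism <- function(dat, spec, config = validation_config(),
                               addon = NULL, tractX = NULL) {
  if (is.character(spec)) spec <- model_specs()[[spec]]
  y <- dat$outcome
  if (anyNA(y)) stop("outcome must be complete (impute first)")
  if ("dti" %in% addon && is.null(tractX))
    stop("tractX is required for the dti add-on")
  n <- nrow(dat)
  set.seed(config$seed)
  fixed_dti <- NULL
  if ("dti" %in% addon && !config$refit_dti) {
    dsm <- fit_dti_lasso(tractX, y, folds = config$cv_folds,
                         repeats = config$cv_repeats, seed = config$seed)
    fixed_dti <- predict(dsm, tractX, type = "logodds")
  }
  full <- train_predict(seq_len(n), dat, y, spec, addon, tractX, config,
                        fixed_dti)
  thr <- if (is.null(config$threshold)) mean(y) else config$threshold
  apparent <- eval_metrics(y, full$p_all, thr)

  draw_idx <- function() {
    if (config$identity_resample) return(seq_len(n))
    if (config$stratified) {
      c(sample(which(y == 1), sum(y == 1), replace = TRUE),
        sample(which(y == 0), sum(y == 0), replace = TRUE))
    } else sample.int(n, n, replace = TRUE)
  }
  mn <- validation_metric_names()
  boot_app <- boot_test <- matrix(NA_real_, config$n_boot, length(mn),
                                  dimnames = list(NULL, mn))
  redraws <- 0L
  for (b in seq_len(config$n_boot)) {
    idx <- draw_idx()
    tries <- 0L
    while (length(unique(y[idx])) < 2L && tries < config$max_redraws) {
      idx <- draw_idx(); tries <- tries + 1L
    }
    redraws <- redraws + tries
    tp <- train_predict(idx, dat, y, spec, addon, tractX, config, fixed_dti)
    thr_b <- if (is.null(config$threshold)) mean(y[idx]) else config$threshold
    boot_app[b, ] <- eval_metrics(y[idx], tp$p_train, thr_b)
    boot_test[b, ] <- eval_metrics(y, tp$p_all, thr_b)
  }
  optim <- colMeans(boot_app - boot_test, na.rm = TRUE)
  unstable <- mn[colSums(is.na(boot_app - boot_test)) > config$n_boot / 2]
  list(apparent = apparent, optimism = optim,
       corrected = apparent - optim,
       boot_test = boot_test, redraws = redraws, unstable = unstable)
}

# boundary-respecting pooling scales per metric, falling back to the
# identity when a value leaves the transform's domain
metric_transform <- function(metric, values) {
  if (metric == "cal_slope" && all(values > 0)) return("log")
  if (metric %in% c("auc", "sensitivity", "specificity", "ppv", "npv") &&
      all(values > 0 & values < 1)) return("logit")
  "identity"
}

#' Internal validation of a model across multiply imputed datasets
#'
#' Runs [bootstrap_optimism()] within each completed dataset and pools the
#' optimism-corrected metrics across imputations by Rubin's rules, using the
#' bootstrap test-performance variance as the within-imputation variance and
#' boundary-respecting transformations per metric (logit for AUC and the
#' classification metrics, log for the calibration slope, identity
#' otherwise).
#'
#' @param spec a `model_spec` or its name.
#' @param imputed an `imputed_set` (or plain list of completed data.frames).
#' @param config a [validation_config()].
#' @param addon add-ons as in [build_design()].
#' @param tractX age-corrected tract matrix aligned to the cohort rows
#'   (identical across imputations; tract data are complete).
#' @return object of class `validation_result`: a data.frame `table` with
#'   one row per metric (apparent, optimism, corrected, 95% interval),
#'   plus the per-imputation detail.
#' @export
validate <- function(spec, imputed, config = validation_config(),
                     addon = NULL, tractX = NULL) {
  datasets <- if (inherits(imputed, "imputed_set")) imputed$datasets else imputed
  m <- length(datasets)
  runs <- vector("list", m)
  for (i in seq_len(m)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    runs[[i]] <- bootstrap_optimism(datasets[[i]], spec, cfg_i, addon, tractX)
  }
  mn <- validation_metric_names()
  tab <- data.frame(metric = mn, apparent = NA_real_, optimism = NA_real_,
                    corrected = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                    stringsAsFactors = FALSE)
  pooled <- list()
  n_complete <- nrow(datasets[[1]])
  for (j in seq_along(mn)) {
    met <- mn[j]
    Q <- vapply(runs, function(r) r$corrected[[met]], numeric(1))
    # corrected R2 is reported on the conventional [-100, 100] percent scale
    if (met == "r2") Q <- pmin(pmax(Q, -100), 100)
    V <- vapply(runs, function(r) {
      stats::var(r$boot_test[, met], na.rm = TRUE)
    }, numeric(1))
    ok <- is.finite(Q) & is.finite(V)
    if (!any(ok)) next
    tr <- metric_transform(met, Q[ok])
    pe <- suppressWarnings(pool_rubin(Q[ok], V[ok], transform = tr,
                                      n_complete = n_complete))
    pooled[[met]] <- pe
    tab$apparent[j] <- mean(vapply(runs, function(r) r$apparent[[met]],
                                   numeric(1)), na.rm = TRUE)
    tab$optimism[j] <- mean(vapply(runs, function(r) r$optimism[[met]],
                                   numeric(1)), na.rm = TRUE)
    tab$corrected[j] <- pe$estimate
    tab$ci_lo[j] <- pe$ci[1]; tab$ci_hi[j] <- pe$ci[2]
  }
  structure(list(
    table = tab, pooled = pooled, runs = runs,
    spec = if (is.character(spec)) spec else spec$name,
    addon = addon, m = m, config = config
  ), class = "validation_result")
}

#' @export
print.validation_result <- function(x, digits = 3, ...) {
  cat("Internal validation:", x$spec,
      if (length(x$addon)) paste0("+ ", paste(x$addon, collapse = " + ")) else "",
      sprintf("(%d bootstrap x %d imputations)\n", x$config$n_boot, x$m))
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) round(v, digits))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Calibration deciles of predicted probabilities
#'
#' Groups subjects into bins of predicted probability and reports the mean
#' prediction and observed event rate per bin (the data behind a calibration
#' plot).
#'
#' @param y binary outcome.
#' @param p predicted probabilities.
#' @param bins number of quantile bins.
#' @return data.frame with `bin`, `n`, `mean_predicted`, `observed_rate`.
#' @export
calibration_deciles <- function(y, p, bins = 10L) {
  br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = bins + 1)))
  g <- cut(p, breaks = br, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(
    bin = sort(unique(g)),
    n = as.integer(table(g)),
    mean_predicted = tapply(p, g, mean),
    observed_rate = tapply(y, g, mean)
  )
  rownames(out) <- NULL
  out
}
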