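#' Fit the lasso DTI score
#'
#' Lasso logistic regression of incomplete recovery on the 96 age-corrected
#' tract metrics (FA and MD for 48 tracts), z-scored with means/SDs from the
#' fitting sample. The penalty is chosen to minimize the mean cross-validated
#' binomial deviance over `repeats` repetitions of `folds`-fold
#' cross-validation with re-randomized folds (lambda-min rule), on a shared
#' grid of 100 log-spaced penalties from the smallest all-zero penalty down
#' to 1e-4 of it; the final model is refit on all rows at the chosen penalty.
#'
#' @param X numeric matrix (subjects x 96 tract metrics), age-corrected but
#'   not yet standardized.
#' @param y binary outcome (incomplete recovery).
#' @param folds,repeats cross-validation folds and repeats.
#' @param seed integer seed for the fold assignments.
#' @param lambda optional fixed penalty, skipping cross-validation (useful
#'   for the fully penalized limit and for path diagnostics).
#' @return object of class `dti_score_model`: standardization `means`/`sds`,
#'   `intercept` and 96 `coefficients` on the z-score scale, chosen `lambda`,
#'   the lambda `grid` and mean CV deviance `cvm`, and the CV specification.
#' @export
fit_dti_lasso <- function(X, y, folds = 10L, repeats = 10L, seed = 1L,
                          lambda = NULL) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (anyNA(X) || anyNA(y)) stop("missing values: run inside a completed dataset")
  if (length(unique(y)) < 2L) stop("both outcome classes are required")
  n <- nrow(X)
  if (n < folds) stop("fewer rows than cross-validation folds")
  means <- colMeans(X)
  sds <- apply(X, 2, stats::sd)
  flat <- sds == 0
  sds[flat] <- 1
  Z <- sweep(sweep(X, 2, means), 2, sds, "/")

  # lambda grid anchored at the smallest penalty that zeroes every slope
  ybar <- mean(y)
  lambda_max <- max(abs(crossprod(Z, y - ybar))) / n
  grid <- exp(seq(log(lambda_max), log(lambda_max * 1e-4), length.out = 100L))

  cvm <- NULL
  if (is.null(lambda)) {
    # seed the fold assignments without disturbing the caller's RNG stream
    # (this function runs inside bootstrap loops that draw their own samples)
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed))
        assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
    cvm <- numeric(length(grid))
    for (r in seq_len(repeats)) {
      foldid <- sample(rep(seq_len(folds), length.out = n))
      cv <- glmnet::cv.glmnet(Z, y, family = "binomial", lambda = grid,
                              foldid = foldid, type.measure = "deviance",
                              standardize = FALSE)
      # align to the requested grid (cv.glmnet may drop trailing lambdas)
      idx <- match(signif(cv$lambda, 10), signif(grid, 10))
      add <- rep(NA_real_, length(grid))
      add[idx] <- cv$cvm
      cvm <- cvm + add
    }
    cvm <- cvm / repeats
    lambda <- grid[which.min(cvm)]
  }

  fit <- glmnet::glmnet(Z, y, family = "binomial",
                        lambda = sort(unique(c(grid, lambda)),
                                      decreasing = TRUE),
                        standardize = FALSE)
  beta <- as.numeric(stats::coef(fit, s = lambda, exact = FALSE))
  names(beta) <- c("(Intercept)", colnames(X))
  structure(list(
    means = means, sds = sds, flat = names(which(flat)),
    intercept = beta[1], coefficients = beta[-1],
    lambda = lambda, grid = grid, cvm = cvm,
    folds = as.integer(folds), repeats = as.integer(repeats),
    seed = as.integer(seed), n = n
  ), class = "dti_score_model")
}

#' @export
print.dti_score_model <- function(x, ...) {
  nz <- sum(x$coefficients != 0)
  cat("Lasso DTI score model\n")
  cat("  n =", x$n, "; predictors:", length(x$coefficients),
      "; selected:", nz, "\n")
  cat("  lambda =", format(x$lambda, digits = 4), "chosen by",
      x$repeats, "x", x$folds, "-fold CV (minimum mean deviance)\n")
  invisible(x)
}

#' @export
coef.dti_score_model <- function(object, ...) {
  c(`(Intercept)` = unname(object$intercept), object$coefficients)
}

#' DTI score for new subjects
#'
#' The score is the model's predicted odds of incomplete recovery from DTI
#' alone, `exp(intercept + sum(beta * z))` with z-scores computed from the
#' standardization constants stored at fit time. The log-odds form is what
#' enters downstream logistic models as the DTI covariate.
#'
#' @param object a `dti_score_model`.
#' @param X matrix of (age-corrected, unstandardized) tract metrics with the
#'   fitted columns.
#' @param type `"logodds"` (default, the downstream covariate), `"odds"`
#'   (the DTI score as reported), or `"prob"`.
#' @param ... unused.
#' @export
predict.dti_score_model <- function(object, X,
                                    type = c("logodds", "odds", "prob"), ...) {
  type <- match.arg(type)
  X <- as.matrix(X)[, names(object$coefficients), drop = FALSE]
  if (anyNA(X)) stop("missing tract values")
  Z <- sweep(sweep(X, 2, object$means), 2, object$sds, "/")
  lp <- object$intercept + drop(Z %*% object$coefficients)
  switch(type, logodds = lp, odds = exp(lp), prob = stats::plogis(lp))
}

#' @rdname predict.dti_score_model
#' @export
dti_score <- function(object, X) predict(object, X, type = "odds")

#' Tract selection frequencies across lasso runs
#'
#' For a collection of fitted DTI-score models (e.g. the bootstrap x
#' imputation grid), the fraction of runs in which each tract's FA / MD
#' coefficient was nonzero, plus their mean, sorted by mean frequency.
#'
#' @param runs list of `dti_score_model` objects.
#' @return data.frame with `tract`, `laterality`, `fa_freq`, `md_freq`,
#'   `mean_freq`, ordered by decreasing mean frequency.
#' @export
selection_frequencies <- function(runs) {
  if (!length(runs)) stop("at least one run is required")
  sel <- sapply(runs, function(m) m$coefficients != 0)  # features x runs
  freq <- rowMeans(sel)
  atlas <- jhu_atlas()
  fa <- freq[paste0("fa_", atlas$slug)]
  md <- freq[paste0("md_", atlas$slug)]
  out <- data.frame(
    tract = atlas$tract,
    laterality = atlas$laterality,
    fa_freq = unname(fa),
    md_freq = unname(md),
    mean_freq = unname((fa + md) / 2),
    stringsAsFactors = FALSE
  )
  out[order(-out$mean_freq, out$tract), , drop = FALSE]
}

#' Whole-brain FA/MD summary
#'
#' Unweighted mean over the 48 tracts per metric.
#'
#' @param tracts tract table.
#' @return data.frame with `subject_id`, `mean_fa`, `mean_md`.
#' @export
whole_brain_summary <- function(tracts) {
  tc <- tract_columns()
  data.frame(
    subject_id = tracts$subject_id,
    mean_fa = rowMeans(as.matrix(tracts[, tc$fa])),
    mean_md = rowMeans(as.matrix(tracts[, tc$md])),
    stringsAsFactors = FALSE
  )
}

#' Pearson correlation of a whole-brain summary with log NFL
#'
#' @param summary numeric whole-brain metric (e.g. `mean_fa`).
#' @param nfl NFL concentrations (pg/ml), strictly positive.
#' @param age if supplied, the age-adjusted variant: the partial correlation
#'   of summary and log NFL given age.
#' @return list with `r`, `p`, `n`, `adjusted`, and a `degenerate` flag when
#'   either variable is constant (r undefined, returned as NA).
#' @export
correlate_log_biomarker <- function(summary, nfl, age = NULL) {
  ok <- !is.na(summary) & !is.na(nfl) & (if (is.null(age)) TRUE else !is.na(age))
  summary <- summary[ok]; nfl <- nfl[ok]
  if (!is.null(age)) age <- age[ok]
  if (any(nfl <= 0)) stop("NFL concentrations must be positive")
  x <- summary; z <- log(nfl)
  adjusted <- !is.null(age)
  if (adjusted) {
    x <- stats::resid(stats::lm(x ~ age))
    z <- stats::resid(stats::lm(z ~ age))
  }
  if (stats::sd(x) == 0 || stats::sd(z) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(x),
                adjusted = adjusted, degenerate = TRUE))
  ct <- stats::cor.test(x, z)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       adjusted = adjusted, degenerate = FALSE)
}
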