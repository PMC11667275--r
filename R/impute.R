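#' Multiple imputation of a cohort by chained equations
#'
#' Fills missing cohort values by iterated conditional draws: predictive mean
#' matching (type-1, 5 donors) for numeric variables, Bayesian logistic draws
#' for binary variables, and multinomial sampling for unordered categorical
#' variables. Every other analysis variable (including the outcome, via GOSE)
#' serves as predictor. The binary `outcome` flag is never imputed directly:
#' GOSE is imputed and `outcome = gose < 8` recomputed, so the invariant holds
#' in every completed dataset.
#'
#' @param cohort clinical data.frame with `NA` marking missing cells.
#' @param m number of completed datasets.
#' @param maxit chained-equation cycles per dataset.
#' @param seed integer seed.
#' @param exclude columns never used (id-like); they are carried through.
#' @return object of class `imputed_set`: `datasets` (list of m completed
#'   data.frames), `m`, `methods` (per imputed variable), `seed`.
#' @export
impute_cohort <- function(cohort, m = 10L, maxit = 10L, seed = 1L,
                          exclude = c("subject_id")) {
  stopifnot(m >= 1L)
  vars <- setdiff(names(cohort), c(exclude, "outcome"))
  n_miss <- vapply(cohort[vars], function(x) sum(is.na(x)), integer(1))
  all_miss <- vars[n_miss == nrow(cohort)]
  if (length(all_miss))
    stop("variable(s) 100% missing, cannot impute: ",
         paste(all_miss, collapse = ", "))
  targets <- vars[n_miss > 0]
  methods <- vapply(targets, function(v) impute_method(cohort[[v]]), character(1))

  if (!length(targets)) {
    message("no missing values; returning ", m, " identical copies")
    return(structure(list(datasets = replicate(m, cohort, simplify = FALSE),
                          m = as.integer(m), methods = character(0),
                          seed = as.integer(seed)),
                     class = "imputed_set"))
  }

  set.seed(seed)
  targets <- targets[order(n_miss[targets])]
  datasets <- vector("list", m)
  for (k in seq_len(m)) {
    comp <- cohort
    # initialize by random draws from the observed margins
    for (v in targets) {
      mis <- is.na(comp[[v]])
      comp[[v]][mis] <- sample(comp[[v]][!mis], sum(mis), replace = TRUE)
    }
    for (cycle in seq_len(maxit)) {
      for (v in targets) {
        mis <- is.na(cohort[[v]])
        X <- impute_design(comp, setdiff(vars, v))
        comp[[v]][mis] <- draw_imputations(
          y = cohort[[v]], y_current = comp[[v]],
          X = X, mis = mis, method = methods[[v]]
        )
      }
    }
    if ("gose" %in% names(comp) && "outcome" %in% names(cohort))
      comp$outcome <- as.integer(comp$gose < 8)
    datasets[[k]] <- comp
  }
  structure(list(datasets = datasets, m = as.integer(m), methods = methods,
                 seed = as.integer(seed)),
            class = "imputed_set")
}

impute_method <- function(x) {
  if (is.character(x) || is.factor(x)) return("categorical")
  u <- unique(x[!is.na(x)])
  if (length(u) <= 2L && all(u %in% c(0, 1))) return("logistic")
  "pmm"
}

# Numeric design matrix from the current completed data; aliased columns
# dropped so downstream solves are full rank.
impute_design <- function(comp, predictors) {
  df <- comp[predictors]
  for (j in seq_along(df)) if (is.character(df[[j]])) df[[j]] <- factor(df[[j]])
  X <- stats::model.matrix(~ ., data = df)
  q <- qr(X)
  X[, q$pivot[seq_len(q$rank)], drop = FALSE]
}

draw_imputations <- function(y, y_current, X, mis, method) {
  obs <- !is.na(y)
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[mis, , drop = FALSE]
  if (method == "pmm") {
    yo <- as.numeric(y[obs])
    fit <- stats::lm.fit(Xo, yo)
    ok <- !is.na(fit$coefficients)
    Xo2 <- Xo[, ok, drop = FALSE]; Xm2 <- Xm[, ok, drop = FALSE]
    beta <- fit$coefficients[ok]
    res <- fit$residuals
    df <- max(length(yo) - sum(ok), 1L)
    sigma2 <- sum(res^2) / stats::rchisq(1, df)
    XtXi <- chol2inv(chol(crossprod(Xo2) + diag(1e-8, ncol(Xo2))))
    beta_star <- beta + drop(t(chol(XtXi)) %*% stats::rnorm(length(beta))) *
      sqrt(sigma2)
    pred_obs <- drop(Xo2 %*% beta)
    pred_mis <- drop(Xm2 %*% beta_star)
    vapply(pred_mis, function(p) {
      d <- sort.int(abs(pred_obs - p), index.return = TRUE)$ix[seq_len(min(5L, length(yo)))]
      yo[sample(d, 1L)]
    }, numeric(1))
  } else if (method == "logistic") {
    yo <- as.numeric(y[obs])
    fit <- suppressWarnings(stats::glm.fit(Xo, yo,
                                           family = stats::binomial()))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    V <- tryCatch({
      W <- fit$weights
      chol2inv(chol(crossprod(Xo * sqrt(W)) + diag(1e-8, ncol(Xo))))
    }, error = function(e) diag(1e-8, ncol(Xo)))
    beta_star <- beta + drop(t(chol(V)) %*% stats::rnorm(length(beta)))
    p <- stats::plogis(drop(Xm %*% beta_star))
    as.numeric(stats::rbinom(length(p), 1, p))
  } else {  # categorical: multinomial sampling from fitted class probabilities
    yo <- factor(y[obs])
    levs <- levels(yo)
    # one-vs-rest logistic scores, normalized; robust for small cohorts
    scores <- sapply(levs, function(l) {
      fit <- suppressWarnings(stats::glm.fit(Xo, as.numeric(yo == l),
                                             family = stats::binomial()))
      b <- fit$coefficients; b[is.na(b)] <- 0
      stats::plogis(drop(Xm %*% b))
    })
    if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
    scores <- scores / rowSums(scores)
    apply(scores, 1, function(p) sample(levs, 1L, prob = p))
  }
}

#' @export
print.imputed_set <- function(x, ...) {
  cat("Multiply imputed set: m =", x$m, "completed datasets\n")
  if (length(x$methods)) {
    cat("  imputed variables:\n")
    for (v in names(x$methods)) cat("   ", v, "->", x$methods[[v]], "\n")
  } else cat("  (no missing values)\n")
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and variances: pooled estimate
#' `Qbar = mean(Q)`, within-variance `W = mean(var)`, between-variance
#' `B = var(Q)`, total `T = W + (1 + 1/m) B`, Barnard-Rubin degrees of
#' freedom, and a t interval. Boundary-respecting transformations are
#' supported: AUC-type quantities pool on the logit scale, ratio-type on the
#' log scale.
#'
#' @param Q per-imputation point estimates.
#' @param var per-imputation (squared-SE) variances; defaults to 0.
#' @param transform `"identity"`, `"logit"` or `"log"`; `Q`/`var` are given
#'   on the original scale, mapped by the delta method, and the interval is
#'   back-transformed.
#' @param conf confidence level.
#' @param n_complete complete-data sample size used for the Barnard-Rubin
#'   small-sample degrees of freedom (`Inf` gives the classic df).
#' @return object of class `pooled_estimate` with `estimate`, `W`, `B`, `T`,
#'   `df`, `ci`, `m`, `transform`.
#' @export
pool_rubin <- function(Q, var = NULL, transform = c("identity", "logit", "log"),
                       conf = 0.95, n_complete = Inf) {
  transform <- match.arg(transform)
  m <- length(Q)
  if (m == 0L) stop("no estimates to pool")
  if (is.null(var)) var <- rep(0, m)
  if (any(var < 0)) stop("variances must be non-negative")
  tr <- switch(transform,
    identity = list(g = identity, ginv = identity, dg = function(q) 1),
    logit = list(g = stats::qlogis, ginv = stats::plogis,
                 dg = function(q) 1 / (q * (1 - q))),
    log = list(g = log, ginv = exp, dg = function(q) 1 / q)
  )
  q_t <- tr$g(Q)
  v_t <- var * tr$dg(Q)^2
  Qbar <- mean(q_t)
  W <- mean(v_t)
  B <- if (m > 1L) stats::var(q_t) else 0
  if (m == 1L) warning("m = 1: between-imputation variance undefined; T = W")
  Tv <- W + (1 + 1 / m) * B
  if (Tv > 0 && B > 0 && m > 1L) {
    lambda <- (1 + 1 / m) * B / Tv
    df_old <- (m - 1) / lambda^2
    if (is.finite(n_complete)) {
      nu_com <- n_complete - 1
      df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
      df <- if (df_obs > 0) 1 / (1 / df_old + 1 / df_obs) else df_old
      df <- max(df, 1)  # keep the t quantile defined when W ~ 0
    } else df <- df_old
  } else df <- Inf
  halfw <- if (Tv > 0) stats::qt(1 - (1 - conf) / 2, df) * sqrt(Tv) else 0
  ci <- tr$ginv(c(Qbar - halfw, Qbar + halfw))
  structure(list(
    estimate = tr$ginv(Qbar), W = W, B = B, T = Tv, df = df,
    ci = ci, m = m, conf = conf, transform = transform
  ), class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (%d%% CI %.4g to %.4g), m = %d",
              x$estimate, round(100 * x$conf), x$ci[1], x$ci[2], x$m))
  if (x$transform != "identity") cat(" [pooled on", x$transform, "scale]")
  cat("\n  W =", format(x$W, digits = 4), " B =", format(x$B, digits = 4),
      " T =", format(x$T, digits = 4), " df =", format(x$df, digits = 4), "\n")
  invisible(x)
}

#' Best- and worst-case outcome sensitivity datasets
#'
#' Missing outcomes are set to complete recovery (GOSE 8) in the best case
#' and to incomplete recovery in the worst case; all other fields untouched.
#'
#' @param cohort clinical data.frame with `gose` and `outcome` columns.
#' @return list with elements `best` and `worst`.
#' @export
best_worst_case <- function(cohort) {
  mis <- is.na(cohort$gose)
  best <- worst <- cohort
  best$gose[mis] <- 8L
  worst$gose[mis] <- 7L
  best$outcome <- as.integer(best$gose < 8)
  worst$outcome <- as.integer(worst$gose < 8)
  list(best = best, worst = worst)
}
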