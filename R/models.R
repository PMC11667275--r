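#' The five reference clinical prognostic models
#'
#' Predictor sets of the published clinical models for incomplete recovery
#' after mild TBI, as refittable specifications. Where the source cohort did
#' not record a variable the published substitutions are encoded: prior
#' mental health problems stand in for prior depression, neck pain and coping
#' styles are omitted, and pupil reactivity is omitted. `ct_positive` in
#' HeadSMART is constant in an all-normal-CT cohort and is auto-pruned as
#' degenerate at design time.
#'
#' @return named list of `model_spec` objects, each with `name`, `predictors`
#'   (character vector; `a:b` denotes a product interaction of numeric
#'   scores).
#' @export
model_specs <- function() {
  mk <- function(name, predictors)
    structure(list(name = name, predictors = predictors), class = "model_spec")
  list(
    `UPFRONT-ED` = mk("UPFRONT-ED", c(
      "age", "sex", "education_level", "prior_mental_health",
      "age:education_level", "alcohol_intoxication", "gcs", "pta_ge_1h"
    )),
    `UPFRONT-PLUS` = mk("UPFRONT-PLUS", c(
      "education_level", "prior_mental_health", "alcohol_intoxication",
      "gcs", "pta_ge_1h", "anxiety", "depression", "symptom_score"
    )),
    HeadSMART = mk("HeadSMART", c(
      "age", "prior_mental_health", "ct_positive", "headache",
      "concentration", "photophobia"
    )),
    `CENTER-ED` = mk("CENTER-ED", c(
      "age", "sex", "prior_mental_health", "asa", "iss", "gcs",
      "injury_mechanism", "symptom_score"
    )),
    `CENTER-PLUS` = mk("CENTER-PLUS", c(
      "age", "prior_mental_health", "iss", "gcs", "injury_mechanism",
      "symptom_score", "ptsd"
    ))
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Reference model", x$name, "\n  predictors:",
      paste(x$predictors, collapse = ", "), "\n")
  invisible(x)
}

#' Build the design matrix for a model specification
#'
#' Categorical variables are expanded to indicator columns against the first
#' (alphabetical) reference level, interactions are products of the numeric
#' component columns, biomarker add-ons enter on the log scale, and the DTI
#' add-on is the log-odds DTI score (column `dti`). Zero-variance columns are
#' dropped with a warning.
#'
#' @param spec a `model_spec` (or its name).
#' @param data completed (no missing values among used columns) data.frame.
#' @param addon optional character vector among `"gfap"`, `"s100b"`, `"nfl"`
#'   (entered as `log(concentration)`) and `"dti"` (a `dti` column of
#'   log-odds must be present).
#' @return numeric design matrix without intercept.
#' @export
build_design <- function(spec, data, addon = NULL) {
  if (is.character(spec)) spec <- model_specs()[[spec]]
  stopifnot(inherits(spec, "model_spec"))
  cols <- list()
  get_var <- function(v) {
    if (v == "ct_positive" && !v %in% names(data))
      return(rep(0, nrow(data)))
    if (!v %in% names(data)) stop("variable missing from data: ", v)
    x <- data[[v]]
    if (anyNA(x)) stop("variable contains missing values: ", v)
    x
  }
  for (term in spec$predictors) {
    if (grepl(":", term, fixed = TRUE)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      vals <- lapply(parts, function(v) as.numeric(get_var(v)))
      cols[[term]] <- Reduce(`*`, vals)
    } else {
      x <- get_var(term)
      if (is.character(x) || is.factor(x)) {
        x <- factor(x)
        levs <- levels(x)
        if (length(levs) < 2L) {
          warning("dropping degenerate (single-level) variable: ", term)
        } else {
          for (l in levs[-1])
            cols[[paste0(term, "_", l)]] <- as.numeric(x == l)
        }
      } else {
        cols[[term]] <- as.numeric(x)
      }
    }
  }
  for (a in addon) {
    if (a %in% c("gfap", "s100b", "nfl")) {
      x <- get_var(a)
      if (any(x <= 0)) stop("biomarker must be positive for the log scale: ", a)
      cols[[paste0("log_", a)]] <- log(x)
    } else if (a == "dti") {
      cols[["dti"]] <- as.numeric(get_var("dti"))
    } else stop("unknown add-on: ", a)
  }
  if (!length(cols))
    stop("empty design: the specification has no predictors and no add-on")
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  degen <- apply(X, 2, function(col) stats::var(col) == 0)
  if (any(degen)) {
    warning("dropping degenerate (constant) column(s): ",
            paste(colnames(X)[degen], collapse = ", "))
    X <- X[, !degen, drop = FALSE]  # 0 columns => intercept-only downstream
  }
  X
}

#' Maximum-likelihood logistic fit
#'
#' @param X design matrix without intercept (the intercept is added).
#' @param y binary outcome.
#' @return object of class `logit_fit`: `coefficients`, `se`, `loglik`, `n`,
#'   `linear_predictor`, `fitted`, `converged`, and a `separation` flag
#'   (perfect separation is flagged, not an error, because it occurs by
#'   chance inside resampling loops).
#' @export
fit_logistic <- function(X, y) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("both outcome classes are required")
  Xi <- cbind(`(Intercept)` = 1, X)
  q <- qr(Xi)
  if (q$rank < ncol(Xi)) {
    keep <- q$pivot[seq_len(q$rank)]
    keep <- sort(keep)
    Xi <- Xi[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(stats::glm.fit(
    Xi, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  p <- fit$fitted.values
  eps <- 1e-12
  ll <- sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  separation <- any(p > 1 - 1e-8 | p < 1e-8) || any(abs(fit$coefficients) > 15)
  if (separation)
    warning("possible (quasi-)separation in logistic fit")
  W <- fit$weights
  V <- tryCatch(chol2inv(chol(crossprod(Xi * sqrt(W)))),
                error = function(e) matrix(NA_real_, ncol(Xi), ncol(Xi)))
  structure(list(
    coefficients = fit$coefficients,
    se = sqrt(diag(V)),
    loglik = ll,
    n = length(y),
    linear_predictor = drop(Xi %*% fit$coefficients),
    fitted = p,
    converged = fit$converged,
    separation = separation,
    columns = colnames(Xi)
  ), class = "logit_fit")
}

#' @export
print.logit_fit <- function(x, ...) {
  cat("Logistic fit: n =", x$n, ", logLik =", format(x$loglik, digits = 6),
      if (x$separation) "(separation flagged)" else "", "\n")
  print(round(cbind(coef = x$coefficients, se = x$se), 4))
  invisible(x)
}

#' Predicted probabilities from a logistic fit on new data
#'
#' @param object a `logit_fit`.
#' @param X design matrix without intercept, with the columns used at fit
#'   time (extra columns are ignored; columns pruned at fit time may be
#'   absent).
#' @param ... unused.
#' @export
predict.logit_fit <- function(object, X, ...) {
  Xi <- cbind(`(Intercept)` = 1, X)
  Xi <- Xi[, object$columns, drop = FALSE]
  stats::plogis(drop(Xi %*% object$coefficients))
}

# log-likelihood of a logistic model with given coefficients
logistic_loglik_at <- function(beta, Xi, y) {
  p <- stats::plogis(drop(Xi %*% beta))
  eps <- 1e-12
  sum(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

#' Likelihood-ratio test of nested logistic models across imputations
#'
#' Pools per-imputation likelihood-ratio statistics by the Meng-Rubin (D3)
#' method: the average LR statistic is recomputed at the across-imputation
#' average coefficients, the two are combined into an F statistic, and the
#' single-dataset case reduces to the classical chi-squared test.
#'
#' @param X_full,X_reduced lists (one per imputation) of design matrices
#'   without intercept; the reduced design's columns must be a subset of the
#'   full design's.
#' @param y_list list of outcome vectors (one per imputation).
#' @return list with `statistic`, `df1`, `df2`, `p_value`, `m`.
#' @export
lrt_nested_mi <- function(X_full, X_reduced, y_list) {
  m <- length(X_full)
  stopifnot(length(X_reduced) == m, length(y_list) == m, m >= 1L)
  if (!all(colnames(X_reduced[[1]]) %in% colnames(X_full[[1]])))
    stop("models are not nested: reduced design has columns absent from the full design")
  k <- ncol(X_full[[1]]) - ncol(X_reduced[[1]])
  if (k == 0L)
    return(list(statistic = 0, df1 = 0, df2 = Inf, p_value = 1, m = m))
  lr <- numeric(m)
  cf_full <- cf_red <- NULL
  for (i in seq_len(m)) {
    ff <- fit_logistic(X_full[[i]], y_list[[i]])
    fr <- fit_logistic(X_reduced[[i]], y_list[[i]])
    lr[i] <- 2 * (ff$loglik - fr$loglik)
    cf_full <- rbind(cf_full, ff$coefficients)
    cf_red <- rbind(cf_red, fr$coefficients)
  }
  if (m == 1L) {
    stat <- max(lr[1], 0)
    return(list(statistic = stat, df1 = k, df2 = Inf,
                p_value = stats::pchisq(stat, k, lower.tail = FALSE), m = m))
  }
  bf <- colMeans(cf_full); br <- colMeans(cf_red)
  lr_bar <- mean(lr)
  lr_tilde <- mean(vapply(seq_len(m), function(i) {
    Xi_f <- cbind(`(Intercept)` = 1, X_full[[i]])[, names(bf), drop = FALSE]
    Xi_r <- cbind(`(Intercept)` = 1, X_reduced[[i]])[, names(br), drop = FALSE]
    2 * (logistic_loglik_at(bf, Xi_f, y_list[[i]]) -
           logistic_loglik_at(br, Xi_r, y_list[[i]]))
  }, numeric(1)))
  r <- max((m + 1) / (k * (m - 1)) * (lr_bar - lr_tilde), 0)
  D <- max(lr_tilde, 0) / (k * (1 + r))
  km <- k * (m - 1)
  df2 <- if (r <= 0) Inf else if (km > 4) {
    4 + (km - 4) * (1 + (1 - 2 / km) / r)^2
  } else {
    km * (1 + 1 / k) * (1 + 1 / r)^2 / 2
  }
  list(statistic = D, df1 = k, df2 = df2,
       p_value = stats::pf(D, k, df2, lower.tail = FALSE), m = m)
}
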