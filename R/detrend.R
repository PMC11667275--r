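#' Fit normal-ageing trajectories on healthy controls
#'
#' One quadratic ordinary-least-squares fit per tract metric, with age
#' entered as centered-and-normalized orthogonal polynomials whose basis
#' constants are stored so the fit predicts reproducibly on new subjects.
#'
#' @param controls control tract table (see [simulate_controls()]).
#' @param reference_age age (years) at which patients are to be re-expressed;
#'   44 is the median patient age in the cohort the defaults emulate.
#' @return object of class `detrend_model`: coefficient matrix (3 x 96),
#'   orthogonal-basis constants, `reference_age`, fitted age range.
#' @export
fit_trajectory <- function(controls, reference_age = 44) {
  tc <- tract_columns()
  feats <- c(tc$fa, tc$md)
  if (!all(feats %in% names(controls)))
    stop("control table lacks the 96 tract columns")
  age <- controls$age
  if (length(age) < 10L)
    stop("need at least 10 controls to fit ageing trajectories")
  if (stats::sd(age) == 0)
    stop("degenerate age spread: all controls have the same age")
  basis <- stats::poly(age, 2)
  coefs <- attr(basis, "coefs")
  Y <- as.matrix(controls[, feats])
  X <- cbind(1, basis)
  beta <- solve(crossprod(X), crossprod(X, Y))  # 3 x 96
  rownames(beta) <- c("intercept", "age1", "age2")
  rng <- range(age)
  if (reference_age < rng[1] || reference_age > rng[2])
    warning("reference age ", reference_age,
            " lies outside the fitted age range [",
            round(rng[1], 1), ", ", round(rng[2], 1), "]")
  structure(list(
    coefficients = beta,
    basis_coefs = coefs,
    reference_age = reference_age,
    age_range = rng,
    features = feats
  ), class = "detrend_model")
}

#' @export
print.detrend_model <- function(x, ...) {
  cat("Control ageing-trajectory model (quadratic, orthogonal basis)\n")
  cat("  features:", length(x$features), "tract metrics\n")
  cat("  fitted age range:", round(x$age_range[1], 1), "-",
      round(x$age_range[2], 1), "years; reference age:",
      x$reference_age, "\n")
  invisible(x)
}

#' Predicted normal tract values at given ages
#'
#' @param object a `detrend_model`.
#' @param age numeric vector of ages.
#' @param ... unused.
#' @return matrix, `length(age)` x 96 tract metrics.
#' @export
predict.detrend_model <- function(object, age, ...) {
  basis <- stats::poly(age, 2, coefs = object$basis_coefs)
  out <- cbind(1, basis) %*% object$coefficients
  colnames(out) <- object$features
  out
}

#' Re-express patient tract metrics at the reference age
#'
#' For each tract metric with observed value `f`, the corrected value is
#' `f + d` where `d = pred(reference_age) - pred(patient_age)` is the normal
#' ageing difference from the control trajectories. Patients already at the
#' reference age are returned unchanged.
#'
#' @param patients patient tract table.
#' @param model a `detrend_model` from [fit_trajectory()].
#' @return the tract table with corrected tract columns; attribute `"audit"`
#'   lists subjects whose age lay outside the fitted range (corrected anyway,
#'   by extrapolation).
#' @export
detrend <- function(patients, model) {
  stopifnot(inherits(model, "detrend_model"))
  if (any(!is.finite(patients$age))) stop("patient ages must be finite")
  d <- matrix(predict(model, model$reference_age), nrow(patients),
              length(model$features), byrow = TRUE) -
    predict(model, patients$age)
  patients[, model$features] <- as.matrix(patients[, model$features]) + d
  extra <- patients$age < model$age_range[1] | patients$age > model$age_range[2]
  attr(patients, "audit") <- list(
    extrapolated = patients$subject_id[extra],
    reference_age = model$reference_age
  )
  patients
}
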