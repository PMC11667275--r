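#' Empirical-Bayes scanner harmonization (parametric ComBat)
#'
#' Removes additive (location) and multiplicative (scale) scanner/batch
#' effects from tract metrics while preserving the variance associated with
#' the supplied biological covariates. This is the parametric location/scale
#' model: each feature is standardized by a pooled covariate regression,
#' per-batch location and scale parameters get Gaussian / inverse-gamma
#' empirical-Bayes priors estimated by method of moments, and the batch
#' parameters are shrunk via iterated conditional posterior means.
#'
#' `fit_combat()` accepts either a tract table (scanner taken from
#' `scanner_id`, features from the 96 `fa_*`/`md_*` columns, default
#' covariate design from [combat_covariates()]) or a plain feature matrix
#' plus an explicit `batch` vector and covariate matrix.
#'
#' @param x tract table data.frame, or numeric matrix (subjects x features).
#' @param batch batch labels (required when `x` is a matrix).
#' @param covariates numeric covariate design matrix (subjects x covariates,
#'   without intercept) whose biological variance should be preserved.
#' @return object of class `combat_model` with the standardization fit
#'   (`grand_mean`, `beta`, `var_pooled`), per-batch empirical-Bayes
#'   `gamma_star` and `delta_star`, the feature and batch labels, and the
#'   names of any constant features that were skipped.
#' @export
fit_combat <- function(x, batch = NULL, covariates = NULL) {
  if (is.data.frame(x)) {
    tc <- tract_columns()
    feats <- c(tc$fa, tc$md)
    if (!all(feats %in% names(x))) stop("tract table lacks the 96 tract columns")
    Y <- as.matrix(x[, feats])
    if (is.null(batch)) batch <- x$scanner_id
    if (is.null(covariates)) covariates <- combat_covariates(x)
  } else {
    Y <- as.matrix(x)
    if (is.null(batch)) stop("batch labels are required for matrix input")
  }
  batch <- as.character(batch)
  if (length(batch) != nrow(Y)) stop("batch length must match rows of x")
  sizes <- table(batch)
  if (any(sizes < 2L))
    stop("singleton batch(es): ", paste(names(sizes)[sizes < 2L], collapse = ", "))
  n <- nrow(Y); p <- ncol(Y)
  batches <- names(sizes)
  B <- vapply(batches, function(b) as.numeric(batch == b), numeric(n))
  colnames(B) <- batches
  mod <- if (is.null(covariates)) NULL else as.matrix(covariates)
  design <- cbind(B, mod)
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    dropped <- colnames(design)[qrd$pivot[(qrd$rank + 1):ncol(design)]]
    stop("covariate design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }

  constant <- apply(Y, 2, function(col) stats::var(col) == 0)
  keep <- which(!constant)
  if (any(constant))
    warning("skipping constant feature(s): ",
            paste(colnames(Y)[constant], collapse = ", "))
  Yk <- Y[, keep, drop = FALSE]

  Bhat <- solve(crossprod(design), crossprod(design, Yk))
  nb <- length(batches)
  grand_mean <- as.vector(crossprod(as.numeric(sizes) / n,
                                    Bhat[seq_len(nb), , drop = FALSE]))
  resid <- Yk - design %*% Bhat
  var_pooled <- colSums(resid^2) / n
  if (any(var_pooled == 0)) {
    zero <- keep[var_pooled == 0]
    warning("skipping feature(s) with zero residual variance: ",
            paste(colnames(Y)[zero], collapse = ", "))
    keep <- setdiff(keep, zero)
    Yk <- Y[, keep, drop = FALSE]
    Bhat <- Bhat[, colnames(Y)[keep], drop = FALSE]
    resid <- resid[, colnames(Y)[keep], drop = FALSE]
    grand_mean <- grand_mean[var_pooled > 0]
    var_pooled <- var_pooled[var_pooled > 0]
  }

  beta <- if (is.null(mod)) NULL else Bhat[-(seq_len(nb)), , drop = FALSE]
  cov_part <- if (is.null(mod)) 0 else mod %*% beta
  stand_mean <- matrix(grand_mean, n, length(keep), byrow = TRUE) + cov_part
  s_data <- (Yk - stand_mean) / matrix(sqrt(var_pooled), n, length(keep),
                                       byrow = TRUE)

  gamma_hat <- t(sapply(batches, function(b) colMeans(s_data[batch == b, , drop = FALSE])))
  delta_hat <- t(sapply(batches, function(b) {
    apply(s_data[batch == b, , drop = FALSE], 2, stats::var)
  }))
  if (length(keep) == 1L) {  # sapply drops to vector
    gamma_hat <- matrix(gamma_hat, nrow = nb)
    delta_hat <- matrix(delta_hat, nrow = nb)
  }

  gamma_star <- gamma_hat
  delta_star <- delta_hat
  for (i in seq_len(nb)) {
    g <- gamma_hat[i, ]; d <- delta_hat[i, ]
    g_bar <- mean(g); t2 <- stats::var(g)
    m <- mean(d); s2 <- stats::var(d)
    a_prior <- (2 * s2 + m^2) / s2
    b_prior <- (m * s2 + m^3) / s2
    ni <- sum(batch == batches[i])
    sd_i <- s_data[batch == batches[i], , drop = FALSE]
    g_new <- g; d_new <- d
    if (length(keep) < 2L || !is.finite(t2) || t2 <= 0 ||
        !is.finite(s2) || s2 <= 0) {
      # degenerate prior (e.g. single feature): fall back to the
      # non-shrunken location/scale estimates
      gamma_star[i, ] <- g
      delta_star[i, ] <- d
      next
    }
    for (iter in seq_len(1000L)) {
      g_old <- g_new; d_old <- d_new
      g_new <- (ni * t2 * g + d_old * g_bar) / (ni * t2 + d_old)
      ss <- colSums((sd_i - matrix(g_new, ni, length(g), byrow = TRUE))^2)
      d_new <- (b_prior + 0.5 * ss) / (ni / 2 + a_prior - 1)
      # relative-change stopping rule, as in the standard EB iteration
      if (max(abs(g_new - g_old) / abs(g_old),
              abs(d_new - d_old) / abs(d_old)) < 1e-4) break
    }
    gamma_star[i, ] <- g_new
    delta_star[i, ] <- d_new
  }
  rownames(gamma_star) <- rownames(delta_star) <- batches
  colnames(gamma_star) <- colnames(delta_star) <- colnames(Y)[keep]

  structure(list(
    features = colnames(Y),
    kept = colnames(Y)[keep],
    skipped = setdiff(colnames(Y), colnames(Y)[keep]),
    batches = batches,
    grand_mean = stats::setNames(grand_mean, colnames(Y)[keep]),
    beta = beta,
    var_pooled = stats::setNames(var_pooled, colnames(Y)[keep]),
    gamma_star = gamma_star,
    delta_star = delta_star,
    covariate_names = colnames(mod)
  ), class = "combat_model")
}

#' @export
print.combat_model <- function(x, ...) {
  cat("ComBat harmonization model\n")
  cat("  features:", length(x$features),
      if (length(x$skipped)) sprintf("(%d skipped as constant)", length(x$skipped)) else "",
      "\n")
  cat("  batches: ", paste(x$batches, collapse = ", "), "\n")
  if (!is.null(x$covariate_names))
    cat("  covariates preserved:", paste(x$covariate_names, collapse = ", "), "\n")
  invisible(x)
}

#' Default ComBat covariate design for a tract table
#'
#' Builds the biological covariates whose variance harmonization must
#' preserve: age, age squared, sex, time since injury, GCS and the traumatic
#' MR-abnormality flag. GCS is looked up in `cohort` by `subject_id`;
#' subjects without a match (healthy controls) get GCS 15.
#'
#' @param tracts tract table.
#' @param cohort optional clinical table supplying GCS.
#' @return numeric design matrix without intercept.
#' @export
combat_covariates <- function(tracts, cohort = NULL) {
  gcs <- rep(15, nrow(tracts))
  if (!is.null(cohort)) {
    idx <- match(tracts$subject_id, cohort$subject_id)
    found <- !is.na(idx) & !is.na(cohort$gcs[idx])
    gcs[found] <- cohort$gcs[idx[found]]
  }
  cbind(
    age = tracts$age,
    age2 = tracts$age^2,
    sex_male = as.numeric(tracts$sex == "M"),
    days_since_injury = tracts$days_since_injury,
    gcs = gcs,
    mr_abnormality = as.numeric(tracts$mr_abnormality)
  )
}

#' Apply a fitted ComBat model
#'
#' Standardizes the data with the stored covariate fit, removes the
#' empirical-Bayes batch location, rescales by the batch scale, and restores
#' the covariate fit. Features skipped at fit time pass through unchanged.
#'
#' @param model a `combat_model`.
#' @param x tract table or feature matrix (same format as at fit time).
#' @param batch,covariates as in [fit_combat()].
#' @return harmonized data in the same shape as `x`.
#' @export
apply_combat <- function(model, x, batch = NULL, covariates = NULL) {
  stopifnot(inherits(model, "combat_model"))
  is_df <- is.data.frame(x)
  if (is_df) {
    Y <- as.matrix(x[, model$features])
    if (is.null(batch)) batch <- x$scanner_id
    if (is.null(covariates)) covariates <- combat_covariates(x)
  } else {
    Y <- as.matrix(x)
    if (is.null(batch)) stop("batch labels are required for matrix input")
  }
  batch <- as.character(batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen))
    stop("batch label(s) not present in the fitted model: ",
         paste(unseen, collapse = ", "))
  n <- nrow(Y)
  kept <- model$kept
  Yk <- Y[, kept, drop = FALSE]
  cov_part <- if (is.null(model$beta)) 0 else {
    as.matrix(covariates) %*% model$beta[, kept, drop = FALSE]
  }
  stand_mean <- matrix(model$grand_mean[kept], n, length(kept), byrow = TRUE) +
    cov_part
  sdv <- matrix(sqrt(model$var_pooled[kept]), n, length(kept), byrow = TRUE)
  s_data <- (Yk - stand_mean) / sdv
  adj <- (s_data - model$gamma_star[batch, kept, drop = FALSE]) /
    sqrt(model$delta_star[batch, kept, drop = FALSE])
  out <- adj * sdv + stand_mean
  Y[, kept] <- out
  if (is_df) {
    x[, model$features] <- Y
    x
  } else Y
}
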