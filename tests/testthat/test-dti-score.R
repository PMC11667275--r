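test_that("the fully penalized model is intercept-only at the prevalence", {
  X <- noise_tractX(200, seed = 1)
  y <- rep(c(1, 0), c(76, 124))  # 38% prevalence
  m <- fit_dti_lasso(X, y, lambda = 1e6)
  expect_true(all(m$coefficients == 0))
  expect_equal(unname(m$intercept), log(0.38 / 0.62), tolerance = 1e-6)
  expect_equal(unname(dti_score(m, X[1, , drop = FALSE])), 0.38 / 0.62,
               tolerance = 1e-6)
})

test_that("the DTI score is exp of the standardized linear predictor", {
  X <- noise_tractX(50, seed = 2)
  m <- fit_dti_lasso(X, rbinom(50, 1, 0.5), lambda = 1e6)
  # hand-built coefficients: intercept 0, one unit coefficient
  m$intercept <- 0
  m$coefficients[] <- 0
  expect_equal(unname(dti_score(m, X[1, , drop = FALSE])), 1)
  m$coefficients["fa_tapetum_l"] <- 1
  x <- X[1, , drop = FALSE]
  x[, "fa_tapetum_l"] <- m$means["fa_tapetum_l"] + m$sds["fa_tapetum_l"]  # z = 1
  expect_equal(unname(dti_score(m, x)), exp(1), tolerance = 1e-12)
  # probability round trip
  odds <- dti_score(m, X)
  expect_equal(unname(odds / (1 + odds)),
               unname(predict(m, X, type = "prob")), tolerance = 1e-12)
  expect_equal(unname(log(odds)), unname(predict(m, X, type = "logodds")),
               tolerance = 1e-12)
})

test_that("informative predictors dominate pure noise in the fitted model", {
  # deviance-minimizing lambda keeps every informative predictor and leaves
  # noise predictors a small minority with small coefficients (lambda-min
  # admits some noise by construction, so sparsity is bounded, not zero)
  hits <- 0L
  informative <- c("fa_uncinate_fasciculus_r", "md_tapetum_l")
  for (s in 1:10) {
    set.seed(100 + s)
    n <- 400
    X <- noise_tractX(n, seed = 200 + s)
    lp <- 1.5 * X[, informative[1]] - 1.5 * X[, informative[2]]
    y <- rbinom(n, 1, plogis(lp))
    m <- suppressWarnings(fit_dti_lasso(X, y, folds = 5, repeats = 2,
                                        seed = s))
    sel <- names(which(m$coefficients != 0))
    top2 <- names(sort(abs(m$coefficients), decreasing = TRUE))[1:2]
    ok <- all(informative %in% sel) &&
      setequal(top2, informative) &&
      length(setdiff(sel, informative)) <= 25
    if (ok) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("duplicated predictors share the single-column coefficient mass", {
  set.seed(3)
  n <- 300
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(1.2 * x))
  X1 <- cbind(a = x, b = rnorm(n))
  X2 <- cbind(a = x, a2 = x, b = X1[, "b"])
  lam <- 0.02
  m1 <- fit_dti_lasso(X1, y, lambda = lam)
  m2 <- fit_dti_lasso(X2, y, lambda = lam)
  expect_equal(unname(m2$coefficients["a"] + m2$coefficients["a2"]),
               unname(m1$coefficients["a"]), tolerance = 1e-3)
})

test_that("the active set shrinks along the penalty path", {
  X <- noise_tractX(153, seed = 5)
  set.seed(5)
  y <- rbinom(153, 1, plogis(1.2 * X[, 1] - X[, 60]))
  m <- fit_dti_lasso(X, y, folds = 5, repeats = 1, seed = 5)
  lams <- m$grid[seq(1, 100, by = 9)]
  nnz <- vapply(lams, function(l) {
    sum(fit_dti_lasso(X, y, lambda = l)$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))  # grid is decreasing in lambda
})

test_that("standardization constants come from the fitting sample only", {
  X <- noise_tractX(120, seed = 6)
  set.seed(6)
  y <- rbinom(120, 1, 0.4)
  m <- fit_dti_lasso(X, y, folds = 5, repeats = 1, seed = 6)
  expect_equal(m$means, colMeans(X))
  # re-applying to the fitting sample is stable under row reordering
  p1 <- predict(m, X, type = "logodds")
  p2 <- predict(m, X[c(2, 1, 3:120), ], type = "logodds")
  expect_equal(p1[1], p2[2])
})

test_that("selection frequencies aggregate and rank correctly", {
  X <- noise_tractX(60, seed = 7)
  m0 <- fit_dti_lasso(X, rbinom(60, 1, 0.5), lambda = 1e6)
  m1 <- m0; m1$coefficients["fa_superior_cerebellar_peduncle_l"] <- 0.5
  tab1 <- selection_frequencies(list(m1))
  expect_equal(tab1$fa_freq[tab1$tract == "Superior cerebellar peduncle L"], 1)
  expect_equal(sum(tab1$fa_freq), 1)
  expect_equal(sum(tab1$md_freq), 0)

  # consistency of the mean column: (0.94 + 0.91) / 2 = 0.925, as in the
  # published table's top row
  runs <- c(replicate(91, {
    m <- m1; m$coefficients["md_superior_cerebellar_peduncle_l"] <- 0.3; m
  }, simplify = FALSE),
  replicate(3, m1, simplify = FALSE),
  replicate(6, {
    m <- m0; m$coefficients["md_superior_cerebellar_peduncle_l"] <- 0.3; m
  }, simplify = FALSE))
  tab <- selection_frequencies(runs)
  row <- tab[tab$tract == "Superior cerebellar peduncle L", ]
  expect_equal(row$fa_freq, 0.94)
  expect_equal(row$md_freq, 0.97)
  expect_equal(row$mean_freq, (0.94 + 0.97) / 2)
  expect_equal(tab$tract[1], "Superior cerebellar peduncle L")
})

test_that("whole-brain summaries and NFL correlation behave", {
  pat <- simulate_patients(quick_config())
  wb <- whole_brain_summary(pat$tracts)
  tc <- tract_columns()
  expect_equal(wb$mean_fa, rowMeans(as.matrix(pat$tracts[tc$fa])))
  # identical FA in all tracts collapses to that value
  flat <- pat$tracts
  flat[tc$fa] <- 0.47
  expect_equal(whole_brain_summary(flat)$mean_fa, rep(0.47, nrow(flat)))

  # generator with NFL = exp(-FA + noise): negative correlation detected
  set.seed(9)
  n <- 150
  fa <- rnorm(n, 0.5, 0.05)
  nfl <- exp(-8 * fa + rnorm(n, 0, 0.2))
  ct <- correlate_log_biomarker(fa, nfl)
  expect_lt(ct$r, 0)
  expect_lt(ct$p, 0.05)
  # age adjustment runs and reports the partial correlation
  ct2 <- correlate_log_biomarker(fa, nfl, age = runif(n, 20, 70))
  expect_true(ct2$adjusted)
  # degenerate and invalid inputs
  expect_true(correlate_log_biomarker(fa, rep(2, n))$degenerate)
  expect_error(correlate_log_biomarker(fa, c(-1, nfl[-1])), "positive")
})
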