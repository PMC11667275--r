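# shared ComBat fixture: shift+scale batch effects over an age trend
combat_fixture <- function(n = 90, p = 30, seed = 1,
                           shift = c(a = 0.03, b = -0.02, c = 0),
                           scale = c(a = 1.4, b = 0.7, c = 1)) {
  set.seed(seed)
  age <- runif(n, 20, 70)
  batch <- rep(names(shift), length.out = n)
  Y <- 0.5 + outer(age, rep(0.002, p)) + shift[batch] +
    scale[batch] * matrix(rnorm(n * p, 0, 0.05), n, p)
  colnames(Y) <- paste0("f", seq_len(p))
  list(Y = Y, age = age, batch = batch,
       mod = cbind(age = age, age2 = age^2))
}

test_that("single batch implies no adjustment direction", {
  fx <- combat_fixture(shift = c(a = 0), scale = c(a = 1))
  m <- fit_combat(fx$Y, batch = fx$batch, covariates = fx$mod)
  expect_lt(max(abs(m$gamma_star)), 1e-8)
  expect_equal(as.vector(m$delta_star), rep(1, ncol(fx$Y)), tolerance = 0.05)
})

test_that("pure location shift between two large batches is removed", {
  set.seed(2)
  n <- 400; p <- 40
  batch <- rep(c("a", "b"), each = n / 2)
  # homogeneous batches: identical within-batch noise law in every feature
  # (empirical Bayes then coincides with the plain location/scale oracle)
  Y <- matrix(rnorm(n * p), n, p)
  for (b in c("a", "b")) {
    i <- batch == b
    Y[i, ] <- scale(Y[i, ]) * 0.05
  }
  Y <- Y + 0.5 + ifelse(batch == "a", 0.05, 0)
  colnames(Y) <- paste0("f", seq_len(p))
  m <- fit_combat(Y, batch = batch)
  adj <- apply_combat(m, Y, batch = batch)
  mean_diff <- colMeans(adj[batch == "a", ]) - colMeans(adj[batch == "b", ])
  expect_lt(max(abs(mean_diff)), 1e-6)
})

test_that("covariate-linked variance is preserved", {
  fx <- combat_fixture(n = 150, seed = 3,
                       shift = c(a = 0, b = 0, c = 0),
                       scale = c(a = 1, b = 1, c = 1))
  m <- fit_combat(fx$Y, batch = fx$batch, covariates = fx$mod)
  adj <- apply_combat(m, fx$Y, batch = fx$batch, covariates = fx$mod)
  sl_in <- coef(lm(fx$Y[, 1] ~ fx$age))[2]
  sl_out <- coef(lm(adj[, 1] ~ fx$age))[2]
  expect_equal(unname(sl_out), unname(sl_in), tolerance = 0.01)
})

test_that("fitting on batch-free data gives an identity-like transform", {
  fx <- combat_fixture(shift = c(a = 0, b = 0, c = 0),
                       scale = c(a = 1, b = 1, c = 1), seed = 4)
  m <- fit_combat(fx$Y, batch = fx$batch, covariates = fx$mod)
  adj <- apply_combat(m, fx$Y, batch = fx$batch, covariates = fx$mod)
  # residual batch structure is pure sampling noise; adjustment is tiny
  expect_lt(max(abs(adj - fx$Y)), 0.05)
  # refitting on adjusted data finds essentially no batch effect left
  m2 <- fit_combat(adj, batch = fx$batch, covariates = fx$mod)
  expect_lt(max(abs(m2$gamma_star)), 0.05)
})

test_that("applying a model to its training data is a fixed point", {
  fx <- combat_fixture(seed = 5)
  m <- fit_combat(fx$Y, batch = fx$batch, covariates = fx$mod)
  adj <- apply_combat(m, fx$Y, batch = fx$batch, covariates = fx$mod)
  m2 <- fit_combat(adj, batch = fx$batch, covariates = fx$mod)
  expect_lt(max(abs(m2$gamma_star)), 0.05)
  expect_equal(as.vector(m2$delta_star),
               rep(1, ncol(fx$Y) * 3), tolerance = 0.1)
})

test_that("harmonized batch means are indistinguishable and slopes survive", {
  cfg <- sim_config(n_patients = 120, n_controls = 100, n_scanners = 2,
                    trajectory_coeffs = flat_trajectories(0.5, -0.001, 0.8, 0.002),
                    batch_shift = list(fa = c(0.05, 0), md = c(-0.06, 0)),
                    batch_scale = c(1.5, 0.8), seed = 6)
  ctr <- simulate_controls(cfg)
  pat <- simulate_patients(cfg)
  joint <- rbind(ctr, pat$tracts)
  cov <- combat_covariates(joint, pat$cohort)
  m <- fit_combat(joint, covariates = cov)
  adj <- apply_combat(m, joint, covariates = cov)
  tc <- tract_columns()
  g1 <- adj$scanner_id == "scanner1"
  pvals <- vapply(c(tc$fa, tc$md), function(col) {
    t.test(adj[[col]][g1], adj[[col]][!g1])$p.value
  }, numeric(1))
  # under the no-batch-difference null, about alpha of BH-adjusted tests
  # may reject; allow 5% of 96
  expect_lte(sum(bh_adjust(pvals) < 0.05), 5)
  # the generating age slope survives harmonization
  fit <- summary(lm(adj[[tc$fa[1]]] ~ poly(adj$age, 2, raw = TRUE) +
                      (adj$sex == "M")))$coefficients
  expect_lt(abs(fit[2, 1] - (-0.001)), 3 * fit[2, 2])
})

test_that("degenerate inputs raise named errors", {
  fx <- combat_fixture()
  expect_error(fit_combat(fx$Y, batch = c("solo", fx$batch[-1])), "solo")
  bad_mod <- cbind(fx$mod, age_copy = fx$mod[, "age"])
  expect_error(fit_combat(fx$Y, batch = fx$batch, covariates = bad_mod),
               "rank deficient")
  m <- fit_combat(fx$Y, batch = fx$batch, covariates = fx$mod)
  expect_error(apply_combat(m, fx$Y, batch = rep("new", nrow(fx$Y)),
                            covariates = fx$mod), "new")
})

test_that("constant features are skipped with a warning and pass through", {
  fx <- combat_fixture()
  Y <- cbind(fx$Y, flat = 0.5)
  expect_warning(m <- fit_combat(Y, batch = fx$batch, covariates = fx$mod),
                 "flat")
  adj <- apply_combat(m, Y, batch = fx$batch, covariates = fx$mod)
  expect_equal(adj[, "flat"], Y[, "flat"])
})

test_that("output matches the reference ComBat implementation", {
  skip_if_not_installed("sva")
  for (s in 1:2) {
    fx <- combat_fixture(seed = 10 + s)
    m <- fit_combat(fx$Y, batch = fx$batch, covariates = fx$mod)
    ours <- apply_combat(m, fx$Y, batch = fx$batch, covariates = fx$mod)
    ref <- t(suppressMessages(sva::ComBat(dat = t(fx$Y), batch = fx$batch,
                                          mod = cbind(1, fx$mod),
                                          par.prior = TRUE)))
    expect_lt(max(abs(ours - ref)), 1e-6)
  }
})
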