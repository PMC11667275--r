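# shared fixture builders (everything is generated in code)

tract_metric_names <- function() {
  atlas <- jhu_atlas()
  c(paste0("fa_", atlas$slug), paste0("md_", atlas$slug))
}

# pure-noise 96-column tract-metric matrix
noise_tractX <- function(n, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * 96), n, 96, dimnames = list(NULL, tract_metric_names()))
}

# minimal deterministic config for fast generator tests
quick_config <- function(...) {
  sim_config(n_patients = 80L, n_controls = 60L, n_scanners = 3L, seed = 11L,
             ...)
}

# flat trajectories with a chosen linear FA slope, zero elsewhere
flat_trajectories <- function(fa_intercept = 0.5, fa_slope = 0,
                              md_intercept = 0.8, md_slope = 0) {
  tr <- default_trajectories()
  tr$fa[, "intercept"] <- fa_intercept
  tr$fa[, "age"] <- fa_slope
  tr$fa[, "age2"] <- 0
  tr$md[, "intercept"] <- md_intercept
  tr$md[, "age"] <- md_slope
  tr$md[, "age2"] <- 0
  tr
}

zero_batch <- function(n_scanners) {
  list(shift = list(fa = rep(0, n_scanners), md = rep(0, n_scanners)),
       scale = rep(1, n_scanners))
}
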