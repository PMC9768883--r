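make_sim <- function(seed = 1, m = NULL, L = 3, J = 4, ...) {
  atlas <- make_atlas(1)
  basis <- harmonic_basis(atlas, L)
  cohort <- table1_cohort()
  if (!is.null(m)) cohort <- cohort[seq_len(m), ]
  tr <- ground_truth(atlas, basis, J = J, ...)
  list(atlas = atlas, basis = basis, cohort = cohort, truth = tr,
       ds = simulate_thickness(atlas, cohort, tr, basis, seed = seed))
}

test_that("spectral transform of a dataset is shape-correct and linear", {
  atlas <- make_atlas(1)
  basis <- harmonic_basis(atlas, 7)
  sim <- make_sim(L = 7, J = 9)
  sp <- transform_dataset(sim$ds, basis)
  expect_identical(dim(sp), c(53L, 64L))
  expect_identical(rownames(sp), sim$ds$cohort$subject)
  # linearity: T(aY1 + bY2) = a T(Y1) + b T(Y2)
  d2 <- simulate_thickness(atlas, sim$cohort, sim$truth, basis, seed = 77)
  mix <- sim$ds
  mix$thickness <- 0.3 * sim$ds$thickness + 0.7 * d2$thickness
  expect_equal(transform_dataset(mix, basis),
               0.3 * sp + 0.7 * transform_dataset(d2, basis),
               tolerance = 1e-10)
  # a constant-zero deviation transforms to zero
  flat <- sim$ds
  flat$thickness[] <- 2.5
  spf <- transform_dataset(flat, basis)
  expect_lt(max(abs(spf[, -1])), 1e-8)
})

test_that("sampler is deterministic given the seed and retains the scheduled draw count", {
  sim <- make_sim(m = 12)
  cfg <- spectral_config(L = 3, J = 4, iterations = 400, burnin = 100,
                         thin = 3, seed = 31)
  f1 <- fit_spectral(sim$ds, cfg)
  f2 <- fit_spectral(sim$ds, cfg)
  expect_identical(f1$samples$B, f2$samples$B)
  expect_identical(f1$samples$theta, f2$samples$theta)
  expect_identical(f1$samples$n_retained, 100L)
  f3 <- fit_spectral(sim$ds, spectral_config(L = 3, J = 4, iterations = 400,
                                             burnin = 100, thin = 3,
                                             seed = 32))
  expect_false(identical(f1$samples$B, f3$samples$B))
  expect_error(spectral_config(iterations = 100, burnin = 200), "burnin")
  expect_error(spectral_config(iterations = 100, burnin = 50, thin = 7),
               "multiple of thin")
  expect_error(spectral_config(J = 20, L = 3), "J must lie")
})

test_that("posterior z-scores summarize spatial draws with sign equivariance", {
  set.seed(8)
  draws <- matrix(stats::rnorm(200 * 5, mean = 2, sd = 1), 200, 5)
  fit <- fake_fit(draws)
  z <- posterior_zscores(fit)
  expect_identical(nrow(z), 5L)
  expect_equal(z$z, colMeans(draws) / apply(draws, 2, stats::sd))
  # constructed draws with per-region mean 2 and sd 1
  two <- matrix(rep(c(1, 3), 50), 100, 4)
  expect_equal(posterior_zscores(fake_fit(two))$z, rep(2 / 1.00503, 4),
               tolerance = 1e-3)
  # negating all draws negates z
  zneg <- posterior_zscores(fake_fit(-draws))
  expect_equal(zneg$z, -z$z)
  # constant draws: degenerate chain error naming the region
  const <- matrix(1.5, 100, 3)
  expect_error(posterior_zscores(fake_fit(const)), "zero posterior sd")
})

test_that("closed-form conjugate posterior is recovered when variances are clamped", {
  # small instance of the fully conjugate configuration
  pts <- fib_points(20)
  b <- harmonic_basis(pts, 3)
  m <- 20; K <- 16
  set.seed(11)
  X <- cbind(intercept = 1, grp = rep(0:1, each = 10))
  truthB <- rbind(stats::rnorm(K, 2, 0.5), stats::rnorm(K, -0.2, 0.2))
  Ytil <- X %*% truthB + matrix(stats::rnorm(m * K, 0, 0.2), m, K)
  s2 <- 0.04; v0 <- 0.5; v1 <- 0.2; d0 <- 0.3; dv <- 0.1
  cfg <- spectral_config(residual = "independent", fe_prior = "gaussian",
                         nonstationary = FALSE, J = 4, L = 3,
                         iterations = 4000, burnin = 1000, thin = 1,
                         seed = 7,
                         fixed = list(resid_var = s2, b0_var = v0,
                                      b_var = v1, delta0_var = d0,
                                      delta_var = dv))
  sm <- run_mcmc(Ytil, X, b$index$l, cfg)
  # oracle: per-frequency Gaussian posterior with beta marginalized
  closed <- matrix(NA_real_, 2, K)
  for (w in seq_len(K)) {
    inL <- w <= 4
    D <- diag(c(v0 + if (inL) d0 else 0, v1 + if (inL) dv else 0))
    A <- crossprod(X) / s2 + solve(D)
    closed[, w] <- solve(A, crossprod(X, Ytil[, w]) / s2)
  }
  est <- apply(sm$B, c(2, 3), mean)
  ses <- matrix(NA_real_, 2, K)
  for (k in 1:2) for (w in seq_len(K)) ses[k, w] <- mcse(sm$B[, k, w])
  expect_lt(stats::median(abs(est - closed) / ses), 1.5)
  expect_lt(max(abs(est - closed) / ses), 4)
  expect_lt(max(abs(est - closed)), 0.02)
})

test_that("horseshoe shrinks null fixed-effect coefficients at least as hard as the gaussian prior", {
  pts <- fib_points(20)
  b <- harmonic_basis(pts, 3)
  m <- 20
  X <- cbind(intercept = 1, grp = rep(0:1, each = 10))
  shrink <- matrix(NA_real_, 20, 2)
  for (rep in 1:20) {
    set.seed(500 + rep)
    Ytil <- cbind(stats::rnorm(m, 2, 0.1),
                  matrix(stats::rnorm(m * 15, 0, 0.3), m, 15))
    for (pr in 1:2) {
      cfg <- spectral_config(residual = "independent",
                             fe_prior = c("gaussian", "horseshoe")[pr],
                             nonstationary = FALSE, J = 4, L = 3,
                             iterations = 800, burnin = 200, thin = 2,
                             seed = 600 + rep)
      sm <- run_mcmc(Ytil, X, b$index$l, cfg)
      shrink[rep, pr] <- mean(abs(apply(sm$B[, 2, ], 2, mean)))
    }
  }
  expect_lt(mean(shrink[, 2]), mean(shrink[, 1]))
})

test_that("posterior z-scores center on zero under a null generator", {
  sim_atlas <- make_atlas(1)
  basis <- harmonic_basis(sim_atlas, 3)
  cohort <- dplyr::filter(table1_cohort(), group %in% c("HC", "LTLE"))
  tr <- ground_truth(sim_atlas, basis, J = 4,
                     effects = list(age = 0, sexM = 0, LTLE = 0, RTLE = 0))
  mean_z <- vapply(1:20, function(rep) {
    ds <- simulate_thickness(sim_atlas, cohort, tr, basis, seed = 700 + rep)
    cfg <- spectral_config(L = 3, J = 4, iterations = 800, burnin = 200,
                           thin = 2, seed = 800 + rep)
    fit <- fit_spectral(ds, cfg)
    mean(posterior_zscores(fit, "LTLE")$z)
  }, 0)
  expect_lt(abs(mean(mean_z)), 0.2)
})
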