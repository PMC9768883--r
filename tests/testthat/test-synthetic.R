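test_that("synthetic atlas is deterministic, balanced, and well separated", {
  a1 <- make_atlas(4)
  a2 <- make_atlas(4)
  expect_identical(a1, a2)
  expect_false(identical(a1, make_atlas(5)))
  expect_identical(nrow(a1), 68L)
  expect_identical(sum(endsWith(a1$region, "_lh")), 34L)
  expect_identical(sum(endsWith(a1$region, "_rh")), 34L)
  expect_identical(anyDuplicated(a1$region), 0L)
  # left-hemisphere centroids live on one longitude half, right on the other
  expect_true(all(a1$longitude[a1$hemisphere == "L"] < pi))
  expect_true(all(a1$longitude[a1$hemisphere == "R"] >= pi))
  # minimum pairwise chordal separation at the default seed
  xyz <- cbind(sin(a1$colatitude) * cos(a1$longitude),
               sin(a1$colatitude) * sin(a1$longitude), cos(a1$colatitude))
  expect_gt(min(stats::dist(xyz)), 0.05)
})

test_that("reference cohort reproduces the demographic table", {
  ch <- table1_cohort()
  expect_identical(nrow(ch), 53L)
  expect_identical(as.integer(table(ch$group)), c(20L, 19L, 14L))
  counts <- table(ch$group, ch$sex)[, c("M", "F")]
  expect_identical(unname(counts["HC", ]), c(10L, 10L))
  expect_identical(unname(counts["LTLE", ]), c(11L, 8L))
  expect_identical(unname(counts["RTLE", ]), c(10L, 4L))
  smry <- cohort_age_summary(ch)
  expect_equal(smry$mean, c(27.95, 32.10, 28.28), tolerance = 1e-6)
  expect_equal(smry$sd, c(6.32, 8.47, 6.28), tolerance = 1e-6)
  # chi-square on its own sex table, ANOVA on its own ages
  expect_equal(round(chisq_homogeneity(counts)$statistic, 2), 1.56)
  raw_aov <- stats::anova(stats::aov(age ~ group, data = ch))
  expect_equal(round(raw_aov$`F value`[1], 2), 1.92)
  expect_identical(table1_cohort(), ch)   # fully deterministic
})

test_that("noise-free generator returns the fixed-effect surface exactly", {
  atlas <- make_atlas(1)
  basis <- harmonic_basis(atlas, 3)
  cohort <- table1_cohort()
  tr <- ground_truth(atlas, basis, J = 4,
                     effects = list(age = 0, sexM = 0, LTLE = 0, RTLE = 0),
                     Sigma = matrix(0, 4, 4), residual = NULL)
  ds <- simulate_thickness(atlas, cohort, tr, basis, seed = 9)
  expect_equal(unname(ds$thickness),
               matrix(tr$baseline, 53, 68, byrow = TRUE))
  # linearity: doubling a true effect doubles the mean group difference
  tr1 <- ground_truth(atlas, basis, J = 4,
                      effects = list(age = 0, sexM = 0, LTLE = -0.2, RTLE = 0),
                      Sigma = matrix(0, 4, 4), residual = NULL)
  tr2 <- ground_truth(atlas, basis, J = 4,
                      effects = list(age = 0, sexM = 0, LTLE = -0.4, RTLE = 0),
                      Sigma = matrix(0, 4, 4), residual = NULL)
  d1 <- simulate_thickness(atlas, cohort, tr1, basis, seed = 9)
  d2 <- simulate_thickness(atlas, cohort, tr2, basis, seed = 9)
  gap <- function(d) {
    colMeans(d$thickness[d$cohort$group == "LTLE", ]) -
      colMeans(d$thickness[d$cohort$group == "HC", ])
  }
  expect_equal(gap(d2), 2 * gap(d1), tolerance = 1e-10)
})

test_that("generated datasets are seed-deterministic and validated", {
  atlas <- make_atlas(1)
  basis <- harmonic_basis(atlas, 3)
  cohort <- table1_cohort()
  tr <- ground_truth(atlas, basis, J = 4)
  d1 <- simulate_thickness(atlas, cohort, tr, basis, seed = 11)
  d2 <- simulate_thickness(atlas, cohort, tr, basis, seed = 11)
  expect_identical(d1$thickness, d2$thickness)
  d3 <- simulate_thickness(atlas, cohort, tr, basis, seed = 12)
  expect_false(identical(d1$thickness, d3$thickness))
  expect_true(all(d1$thickness > 0))
})

test_that("empirical residual covariance matches the Matern sampling model", {
  # the generator's noise path against the analytic covariance: many
  # replicate subjects with identical covariates, all effects zero
  atlas <- make_atlas(1)[seq(1, 68, by = 5), ]   # 14 regions for speed
  basis <- harmonic_basis(atlas, 2)
  nrep <- 20000
  cohort <- tibble::tibble(
    subject = sprintf("r%05d", seq_len(nrep)),
    group = factor(rep("HC", nrep), levels = c("HC", "LTLE", "RTLE")),
    age = rep(30, nrep), sex = rep("M", nrep)
  )
  pars <- matern_params(0.05, 0.1, 0.6, 1.0)   # keeps all values positive
  tr <- ground_truth(atlas, basis, J = 2,
                     effects = list(age = 0, sexM = 0, LTLE = 0, RTLE = 0),
                     Sigma = matrix(0, 2, 2), residual = pars)
  ds <- simulate_thickness(atlas, cohort, tr, basis, seed = 21)
  E <- sweep(ds$thickness, 2, tr$baseline)
  emp <- crossprod(E) / nrep
  ana <- matern_covariance(atlas, pars)
  # Monte-Carlo SE of a covariance entry: sqrt((Cii Cjj + Cij^2)/n)
  se <- sqrt((outer(diag(ana), diag(ana)) + ana^2) / nrep)
  expect_lt(max(abs(emp - ana) / se), 4.5)   # max over 105 entries
  # marginal variance decomposition with random effects switched on
  tr2 <- ground_truth(atlas, basis, J = 2,
                      effects = list(age = 0, sexM = 0, LTLE = 0, RTLE = 0),
                      Sigma = diag(0.02, 2), residual = pars)
  ds2 <- simulate_thickness(atlas, cohort, tr2, basis, seed = 22)
  Z <- basis$matrix[, 1:2]
  for (j in c(1, 7, 14)) {
    analytic <- pars$sigma2 + pars$tau2 + sum(Z[j, ]^2 * 0.02)
    expect_equal(stats::var(ds2$thickness[, j]), analytic,
                 tolerance = 0.05)
  }
})

test_that("dataset constructor rejects misaligned and invalid inputs", {
  ds <- toy_dataset()
  expect_error(thickness_dataset(ds$thickness[-1, ], ds$cohort, ds$atlas),
               "do not match")
  th_bad <- ds$thickness; th_bad[2, 3] <- NA
  expect_error(thickness_dataset(th_bad, ds$cohort, ds$atlas),
               "missing thickness value at subject s02")
  th_neg <- ds$thickness; th_neg[1, 1] <- -0.1
  expect_error(thickness_dataset(th_neg, ds$cohort, ds$atlas), "positive")
  # column/row reordering is healed by label alignment
  perm <- ds$thickness[rev(seq_len(nrow(ds$thickness))),
                       sample(ncol(ds$thickness))]
  ds2 <- thickness_dataset(perm, ds$cohort, ds$atlas)
  expect_identical(ds2$thickness, ds$thickness)
})
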