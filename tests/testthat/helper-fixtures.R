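# Quasi-uniform (Fibonacci lattice) points: well-conditioned scattered
# designs for transform tests.
fib_points <- function(n) {
  i <- seq_len(n)
  z <- 1 - 2 * (i - 0.5) / n
  sphere_points(acos(z), ((i - 1) * pi * (3 - sqrt(5))) %% (2 * pi))
}

# Tiny thickness dataset built from explicit matrices (no spatial noise).
toy_dataset <- function(m = 6, seed = 1) {
  atlas <- make_atlas(1)
  cohort <- tibble::tibble(
    subject = sprintf("s%02d", seq_len(m)),
    group = factor(rep(c("HC", "LTLE"), length.out = m),
                   levels = c("HC", "LTLE", "RTLE")),
    age = seq(25, 40, length.out = m),
    sex = rep(c("M", "F"), length.out = m)
  )
  set.seed(seed)
  th <- matrix(stats::rnorm(m * 68, 2.7, 0.15), m, 68,
               dimnames = list(cohort$subject, atlas$region))
  thickness_dataset(th, cohort, atlas)
}

# Minimal spectral_fit stand-in for summary-level functions: supply the
# spatial-domain draws directly through an identity basis.
fake_fit <- function(draws, covariate = "LTLE") {
  n <- ncol(draws)
  atlas <- make_atlas(1)[seq_len(n), ]
  basis <- list(L = NA, matrix = diag(n), index = NULL, points = atlas)
  class(basis) <- "harmonic_basis"
  structure(list(
    samples = list(B = array(draws, c(nrow(draws), 1, n),
                             dimnames = list(NULL, covariate, NULL)),
                   covariates = covariate, n_retained = nrow(draws)),
    basis = basis, atlas = atlas,
    cohort = NULL, config = NULL
  ), class = "spectral_fit")
}

# Batch-means Monte-Carlo standard error for a (possibly autocorrelated)
# chain of draws.
mcse <- function(x, nb = 40) {
  nb <- min(nb, floor(length(x) / 4))
  use <- nb * floor(length(x) / nb)
  bm <- colMeans(matrix(x[seq_len(use)], ncol = nb))
  stats::sd(bm) / sqrt(nb)
}
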