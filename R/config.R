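#' Model configuration
#'
#' Assembles and validates the settings of the spectral Bayesian model: the
#' residual spectral structure, the fixed-effect shrinkage prior, whether
#' subject-level nonstationary random effects are included, the basis sizes
#' and the MCMC schedule.
#'
#' The default schedule (5,000 iterations, 1,000 burn-in, thin 4) is a
#' desk-scale setting for simulation work; `preset = "paper"` switches to
#' the long schedule (100,000 iterations, 10,000 burn-in, thin 10) with
#' L = 7 and J = 9.
#'
#' @param residual `"matern"` (degree-dependent spectral variances from the
#'   Matern spectral density) or `"independent"` (flat variance across
#'   frequencies). Applies to the residual process and both fixed-effect
#'   process priors.
#' @param fe_prior `"gaussian"` or `"horseshoe"` prior on the fixed-effect
#'   basis coefficients `beta_kj` (covariates, not the intercept).
#' @param nonstationary Include the subject random effects `Z~ gamma` in the
#'   likelihood for the low-frequency window?
#' @param J Size of the low-frequency window (basis coefficient count).
#' @param L Maximum harmonic degree; the spectral dimension is `(L+1)^2`.
#' @param iterations,burnin,thin MCMC schedule; `(iterations - burnin)` must
#'   be a positive multiple of `thin`.
#' @param seed Integer RNG seed for the sampler.
#' @param epsilon Prior hyperconstant for the InvGamma and log-range priors.
#' @param fixed Optional named list clamping variance blocks instead of
#'   sampling them (used for conjugate-oracle checks): any of `resid_var`,
#'   `b0_var`, `b_var` (scalar spectral variances, flat in degree) and
#'   `delta0_var`, `delta_var` (basis-coefficient prior variances).
#' @param preset `"demo"` (defaults as given) or `"paper"`.
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(residual = c("matern", "independent"),
                            fe_prior = c("gaussian", "horseshoe"),
                            nonstationary = TRUE,
                            J = 9L, L = 7L,
                            iterations = 5000L, burnin = 1000L, thin = 4L,
                            seed = 1L, epsilon = 0.1,
                            fixed = list(),
                            preset = c("demo", "paper")) {
  preset <- match.arg(preset)
  if (preset == "paper") {
    if (missing(iterations)) iterations <- 100000L
    if (missing(burnin)) burnin <- 10000L
    if (missing(thin)) thin <- 10L
    if (missing(J)) J <- 9L
    if (missing(L)) L <- 7L
  }
  cfg <- list(
    residual = match.arg(residual),
    fe_prior = match.arg(fe_prior),
    nonstationary = isTRUE(nonstationary),
    J = as.integer(J), L = as.integer(L),
    iterations = as.integer(iterations), burnin = as.integer(burnin),
    thin = as.integer(thin), seed = as.integer(seed),
    epsilon = epsilon, fixed = fixed, preset = preset
  )
  validate_config(cfg)
  structure(cfg, class = "spectral_config")
}

validate_config <- function(cfg) {
  if (cfg$burnin >= cfg$iterations) stop("burnin must be < iterations")
  if (cfg$burnin < 0L || cfg$thin < 1L) stop("invalid MCMC schedule")
  if ((cfg$iterations - cfg$burnin) %% cfg$thin != 0L) {
    stop("(iterations - burnin) must be a multiple of thin")
  }
  if (cfg$L < 0L) stop("L must be >= 0")
  if (cfg$J < 1L || cfg$J > (cfg$L + 1L)^2) {
    stop("J must lie in [1, (L+1)^2]")
  }
  if (cfg$epsilon <= 0) stop("epsilon must be > 0")
  invisible(cfg)
}

#' @export
print.spectral_config <- function(x, ...) {
  cat(sprintf(
    "<spectral_config> residual=%s fe_prior=%s nonstationary=%s J=%d L=%d\n  schedule: %d iterations, %d burn-in, thin %d (seed %d)\n",
    x$residual, x$fe_prior, x$nonstationary, x$J, x$L,
    x$iterations, x$burnin, x$thin, x$seed))
  invisible(x)
}

#' The 16-configuration comparison grid
#'
#' All combinations of residual structure (independent / matern),
#' fixed-effect prior (gaussian / horseshoe), nonstationary random effects
#' (no / yes) and window size (J = 4 / 9), in the canonical report order:
#' residual slowest, then prior, then nonstationarity, then J.
#'
#' @param ... Further arguments (schedule, seed, L) passed to every
#'   [spectral_config()].
#' @return A tibble with columns `residual`, `fe_prior`, `nonstationary`,
#'   `J` and a list-column `config` of 16 `spectral_config` objects.
#' @export
config_grid <- function(...) {
  g <- tidyr::expand_grid(
    residual = c("independent", "matern"),
    fe_prior = c("gaussian", "horseshoe"),
    nonstationary = c(FALSE, TRUE),
    J = c(4L, 9L)
  )
  g$config <- purrr::pmap(g, function(residual, fe_prior, nonstationary, J) {
    spectral_config(residual = residual, fe_prior = fe_prior,
                    nonstationary = nonstationary, J = J, ...)
  })
  g
}
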