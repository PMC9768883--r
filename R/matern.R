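#' Matern residual parameters
#'
#' Container for the four parameters of the residual covariance: nugget
#' variance `sigma2` (mm^2), spatial variance `tau2` (mm^2), range `phi`
#' (unit-sphere chordal distance) and smoothness `nu`.
#'
#' @param sigma2 Nugget variance, `>= 0`.
#' @param tau2 Spatially structured variance, `>= 0` (`sigma2 + tau2 > 0`).
#' @param phi Range, `> 0`.
#' @param nu Smoothness, `> 0`.
#' @return A list of class `matern_params`.
#' @export
matern_params <- function(sigma2, tau2, phi, nu) {
  vals <- c(sigma2 = sigma2, tau2 = tau2, phi = phi, nu = nu)
  if (any(!is.finite(vals))) stop("matern_params requires finite values")
  if (sigma2 < 0 || tau2 < 0) stop("variances must be >= 0")
  if (sigma2 + tau2 <= 0) stop("sigma2 + tau2 must be > 0")
  if (phi <= 0 || nu <= 0) stop("phi and nu must be > 0")
  structure(list(sigma2 = sigma2, tau2 = tau2, phi = phi, nu = nu),
            class = "matern_params")
}

#' @export
print.matern_params <- function(x, ...) {
  cat(sprintf("<matern_params> sigma2=%.4g tau2=%.4g phi=%.4g nu=%.4g\n",
              x$sigma2, x$tau2, x$phi, x$nu))
  invisible(x)
}

#' Matern correlation
#'
#' `M(d) = 2^(1-nu)/Gamma(nu) * (3d/phi)^nu * K_nu(3d/phi)`, with `M(0) = 1`
#' by the limit. `K_nu` is the modified Bessel function of the second kind.
#' The scaling means the correlation drops to about 0.05 at `d = phi` when
#' `nu = 1/2`, giving the range an interpretable unit.
#'
#' @param d Distances, `>= 0` (vectorized).
#' @param phi Range, `> 0`.
#' @param nu Smoothness, `> 0`.
#' @return Correlations in `(0, 1]`.
#' @export
matern_correlation <- function(d, phi, nu) {
  if (phi <= 0 || nu <= 0) stop("matern_correlation requires phi > 0, nu > 0")
  if (any(d < 0)) stop("distances must be >= 0")
  u <- 3 * d / phi
  out <- numeric(length(u))
  zero <- u < 1e-14
  out[zero] <- 1
  if (any(!zero)) {
    uu <- u[!zero]
    # evaluate in log space; besselK(expon.scaled) avoids underflow at large u
    out[!zero] <- exp((1 - nu) * log(2) - lgamma(nu) + nu * log(uu) +
                        log(besselK(uu, nu, expon.scaled = TRUE)) - uu)
  }
  out
}

#' Matern covariance matrix at spherical points
#'
#' Entry (i, j) is `sigma2 * 1[i == j] + tau2 * M(chordal distance ij)`,
#' using the chordal (through-the-sphere) distance between the unit vectors
#' of the points, which keeps the Matern family positive definite on the
#' sphere for every smoothness.
#'
#' @param points A `sphere_points()` tibble (or atlas with angle columns).
#' @param params A `matern_params` object.
#' @return A symmetric covariance matrix with diagonal `sigma2 + tau2`.
#' @export
matern_covariance <- function(points, params) {
  stopifnot(inherits(params, "matern_params"))
  if (nrow(points) < 1L) stop("matern_covariance requires at least one point")
  xyz <- sphere_to_xyz(points)
  d <- as.matrix(stats::dist(xyz))
  C <- params$tau2 * matern_correlation(as.vector(d), params$phi, params$nu)
  C <- matrix(C, nrow(d), ncol(d))
  diag(C) <- diag(C) + params$sigma2
  (C + t(C)) / 2
}

#' Spectral variance of the Matern-plus-nugget process
#'
#' Variance of the degree-`l` harmonic coefficient implied by the spatial
#' covariance: `lambda(l) = sigma2 + tau2 * c * (alpha^2 + l(l+1))^-(nu+1)`
#' with `alpha = 3/phi` and `c` the constant normalizing the discrete
#' spectral measure `sum_{l<=50} (2l+1) c (alpha^2+l(l+1))^-(nu+1)` to one,
#' so that with no nugget the coefficient variances integrate back to
#' `tau2`. Isotropy makes it a function of the degree only.
#'
#' @param l Harmonic degrees, integers `>= 0` (vectorized).
#' @param params A `matern_params` object.
#' @return Nonnegative variances, one per degree.
#' @export
matern_spectral_density <- function(l, params) {
  stopifnot(inherits(params, "matern_params"))
  if (any(l < 0)) stop("degrees must be >= 0")
  params$sigma2 + params$tau2 * spectral_shape(l, params$phi, params$nu)
}

# Normalized spectral shape c * (alpha^2 + l(l+1))^-(nu+1); sums (with 2l+1
# multiplicity) to 1 over degrees 0..50.
spectral_shape <- function(l, phi, nu, L_norm = 50L) {
  alpha2 <- (3 / phi)^2
  ln <- 0:L_norm
  g <- (alpha2 + ln * (ln + 1))^(-(nu + 1))
  cnorm <- 1 / sum((2 * ln + 1) * g)
  cnorm * (alpha2 + l * (l + 1))^(-(nu + 1))
}

#' Unconstrained re-parameterization of the Matern parameters
#'
#' Maps `(sigma2, tau2, phi, nu)` to the sampling scale: total variance
#' `v = sigma2 + tau2`, logit spatial proportion
#' `r = logit(tau2 / (sigma2 + tau2))`, log range `log_phi`, and log
#' smoothness `log_nu`. A zero nugget or zero spatial variance would send
#' `r` to infinity; it is clamped at +/-30 with a warning.
#'
#' @param params A `matern_params` object.
#' @return A list of class `matern_reparam` with `v`, `r`, `log_phi`, `log_nu`.
#' @export
matern_reparam <- function(params) {
  stopifnot(inherits(params, "matern_params"))
  v <- params$sigma2 + params$tau2
  p <- params$tau2 / v
  if (p <= 0 || p >= 1) {
    warning("degenerate variance split; clamping logit proportion to +/-30")
    r <- if (p <= 0) -30 else 30
  } else {
    r <- stats::qlogis(p)
  }
  structure(list(v = v, r = r, log_phi = log(params$phi),
                 log_nu = log(params$nu)),
            class = "matern_reparam")
}

#' Inverse of [matern_reparam()]
#'
#' @param rp A `matern_reparam` object (or list with `v`, `r`, `log_phi`,
#'   `log_nu`).
#' @return A `matern_params` object.
#' @export
matern_unreparam <- function(rp) {
  p <- stats::plogis(rp$r)
  matern_params(sigma2 = rp$v * (1 - p), tau2 = rp$v * p,
                phi = exp(rp$log_phi), nu = exp(rp$log_nu))
}
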