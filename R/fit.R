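#' Transform a thickness dataset to the spectral domain
#'
#' Applies the forward spherical-harmonic transform to every subject's
#' regional thickness profile, de-correlating the spatial signal. Linear,
#' so the spatial model carries over coefficient-by-coefficient.
#'
#' @param ds A `thickness_dataset`.
#' @param basis A `harmonic_basis` built at the dataset's atlas centroids.
#' @return A subjects x `(L+1)^2` numeric matrix of real spectral
#'   coefficients, rows named by subject.
#' @export
transform_dataset <- function(ds, basis) {
  stopifnot(inherits(ds, "thickness_dataset"), inherits(basis, "harmonic_basis"))
  if (nrow(basis$matrix) != ncol(ds$thickness)) {
    stop("basis points do not align with the dataset regions")
  }
  sht_forward(ds$thickness, basis)
}

#' Fit the spectral Bayesian model to a thickness dataset
#'
#' End-to-end fit: builds the harmonic basis at the atlas centroids,
#' transforms the data to the spectral domain, assembles the design matrix
#' (intercept, centered age, sex, LTLE and RTLE dummies with HC baseline)
#' and runs the MCMC sampler.
#'
#' @param ds A `thickness_dataset`.
#' @param config A [spectral_config()].
#' @return An object of class `spectral_fit` wrapping the posterior samples
#'   together with the basis, atlas and design information needed for
#'   spatial-domain summaries and prediction.
#' @examples
#' \donttest{
#' atlas <- make_atlas(1)
#' basis <- harmonic_basis(atlas, L = 3)
#' truth <- ground_truth(atlas, basis, J = 4)
#' ds <- simulate_thickness(atlas, table1_cohort(), truth, basis)
#' fit <- fit_spectral(ds, spectral_config(L = 3, J = 4, iterations = 600,
#'                                         burnin = 200, thin = 2))
#' tidy(fit)
#' }
#' @export
fit_spectral <- function(ds, config = spectral_config()) {
  stopifnot(inherits(ds, "thickness_dataset"))
  basis <- harmonic_basis(ds$atlas, config$L)
  spectral <- transform_dataset(ds, basis)
  X <- design_matrix(ds$cohort)
  samples <- run_mcmc(spectral, X, basis$index$l, config)
  structure(list(
    samples = samples, basis = basis, atlas = ds$atlas, cohort = ds$cohort,
    config = config, age_center = attr(X, "age_center"),
    covariates = colnames(X)
  ), class = "spectral_fit")
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("<spectral_fit>", nrow(x$cohort), "subjects,", nrow(x$atlas),
      "regions, L =", x$config$L, ", J =", x$config$J, "\n ",
      x$samples$n_retained, "retained draws (", x$config$iterations,
      "iterations, burn-in", x$config$burnin, ", thin", x$config$thin, ")\n")
  invisible(x)
}

# draws x regions matrix of the spatial-domain coefficient surface for one
# covariate.
spatial_draws <- function(fit, covariate) {
  k <- match(covariate, fit$samples$covariates)
  if (is.na(k)) stop("unknown covariate: ", covariate)
  fit$samples$B[, k, , drop = TRUE] %*% t(fit$basis$matrix)
}

#' Posterior z-score maps
#'
#' Transforms every retained draw of each spectral coefficient surface back
#' to the spatial domain and summarizes it per region: posterior mean,
#' posterior SD, and their ratio, the posterior z-score. Strongly negative
#' z-scores flag cortical thinning associated with the covariate.
#'
#' @param fit A `spectral_fit`.
#' @param covariates Which covariate surfaces to summarize (default: all
#'   but the intercept).
#' @return A tibble: `covariate`, `region`, `hemisphere`, `mean` (mm per
#'   covariate unit), `sd`, `z`.
#' @export
posterior_zscores <- function(fit, covariates = NULL) {
  stopifnot(inherits(fit, "spectral_fit"))
  if (fit$samples$n_retained < 2L) stop("need at least 2 retained draws")
  if (is.null(covariates)) covariates <- setdiff(fit$samples$covariates,
                                                 "intercept")
  purrr::map_dfr(covariates, function(cv) {
    dr <- spatial_draws(fit, cv)
    mu <- colMeans(dr)
    sd <- apply(dr, 2, stats::sd)
    if (any(sd == 0)) {
      stop("degenerate chain: zero posterior sd at region ",
           fit$atlas$region[which(sd == 0)[1]], " (covariate ", cv, ")")
    }
    tibble::tibble(covariate = cv, region = fit$atlas$region,
                   hemisphere = fit$atlas$hemisphere,
                   mean = mu, sd = sd, z = mu / sd)
  })
}

#' Posterior predictive mean thickness for new subjects
#'
#' Expected regional thickness for subjects described by covariates only:
#' the posterior mean fixed-effect surface evaluated at each subject's
#' design row, with the subject random effects at their prior mean (zero),
#' mapped back to the regions by the inverse transform.
#'
#' @param object A `spectral_fit`.
#' @param newdata A cohort tibble (`subject`, `group`, `age`, `sex`). Ages
#'   are centered at the training-sample mean.
#' @param ... Unused.
#' @return A subjects x regions matrix of predicted thickness (mm).
#' @export
predict.spectral_fit <- function(object, newdata, ...) {
  validate_cohort(newdata)
  X <- design_matrix(newdata, center = object$age_center)
  Bbar <- apply(object$samples$B, c(2, 3), mean)   # covariates x frequencies
  pred <- (X %*% Bbar) %*% t(object$basis$matrix)
  dimnames(pred) <- list(newdata$subject, object$atlas$region)
  pred
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a spectral fit
#'
#' One row per covariate per region with the posterior mean, SD and
#' z-score of the spatially varying coefficient (the [posterior_zscores()]
#' table, in broom column conventions).
#'
#' @param x A `spectral_fit`.
#' @param ... Passed to [posterior_zscores()].
#' @return A tibble with columns `term`, `region`, `hemisphere`,
#'   `estimate`, `std.error`, `statistic`.
#' @export
tidy.spectral_fit <- function(x, ...) {
  z <- posterior_zscores(x, ...)
  tibble::tibble(term = z$covariate, region = z$region,
                 hemisphere = z$hemisphere, estimate = z$mean,
                 std.error = z$sd, statistic = z$z)
}

#' One-row fit summary
#'
#' @param x A `spectral_fit`.
#' @param ... Unused.
#' @return A one-row tibble: subjects, regions, spectral dimension, draw
#'   counts and Metropolis acceptance rates.
#' @export
glance.spectral_fit <- function(x, ...) {
  tibble::tibble(
    n_subjects = nrow(x$cohort), n_regions = nrow(x$atlas),
    n_frequencies = ncol(x$basis$matrix),
    iterations = x$config$iterations, burnin = x$config$burnin,
    thin = x$config$thin, n_retained = x$samples$n_retained,
    accept_residual = x$samples$accept$residual,
    accept_intercept = x$samples$accept$intercept,
    accept_slope = x$samples$accept$slope
  )
}

#' Map plot of posterior z-scores
#'
#' Plots each region at its atlas centroid (longitude x colatitude, one
#' panel per covariate), colored by posterior z-score; a diverging scale
#' centered at zero, so thinning effects show on the negative side.
#'
#' @param object A `spectral_fit`.
#' @param ... Passed to [posterior_zscores()].
#' @return A ggplot object.
#' @export
autoplot.spectral_fit <- function(object, ...) {
  z <- posterior_zscores(object, ...)
  z <- dplyr::left_join(z, object$atlas, by = c("region", "hemisphere"))
  ggplot2::ggplot(z, ggplot2::aes(x = .data$longitude,
                                  y = .data$colatitude,
                                  color = .data$z)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_color_gradient2(low = "#b2182b", mid = "grey85",
                                   high = "#2166ac", midpoint = 0) +
    ggplot2::facet_wrap(~covariate) +
    ggplot2::labs(x = "longitude (rad)", y = "colatitude (rad)",
                  color = "posterior z") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Persist posterior samples as delimited text
#'
#' Writes the retained draws to a directory: one long-format TSV per
#' parameter block (`B.tsv` spectral fixed effects, `beta.tsv` basis
#' coefficients, `theta.tsv` variance blocks, `Sigma.tsv` if present) plus
#' a YAML manifest with the config, seed and Metropolis acceptance rates.
#'
#' @param fit A `spectral_fit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_samples <- function(fit, dir) {
  stopifnot(inherits(fit, "spectral_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  long <- function(arr, value_names) {
    d <- dim(arr)
    out <- tibble::tibble(
      draw = rep(seq_len(d[1]), times = d[2] * d[3]),
      covariate = rep(rep(fit$samples$covariates, each = d[1]), times = d[3]),
      column = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = as.vector(arr)
    )
    out
  }
  readr::write_tsv(long(fit$samples$B), file.path(dir, "B.tsv"))
  readr::write_tsv(long(fit$samples$beta), file.path(dir, "beta.tsv"))
  readr::write_tsv(fit$samples$theta, file.path(dir, "theta.tsv"))
  if (!is.null(fit$samples$Sigma)) {
    d <- dim(fit$samples$Sigma)
    readr::write_tsv(tibble::tibble(
      draw = rep(seq_len(d[1]), times = d[2] * d[3]),
      row = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
      col = rep(seq_len(d[3]), each = d[1] * d[2]),
      value = as.vector(fit$samples$Sigma)
    ), file.path(dir, "Sigma.tsv"))
  }
  yaml::write_yaml(list(
    config = unclass(fit$config)[c("residual", "fe_prior", "nonstationary",
                                   "J", "L", "iterations", "burnin", "thin",
                                   "seed", "epsilon")],
    accept = fit$samples$accept,
    n_retained = fit$samples$n_retained
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
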