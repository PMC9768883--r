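#' Credible-interval recovery study on synthetic cohorts
#'
#' Simulates cohorts carrying a known smooth negative group-effect surface
#' (a harmonic bump, so the truth is representable at the working degree),
#' fits the spectral model to each replicate and reports the empirical
#' coverage of equal-tailed credible intervals for the effect surface at
#' the regions where the true deficit is substantial.
#'
#' @param nrep Number of replicate cohorts.
#' @param m Subjects per cohort (split evenly HC / LTLE).
#' @param level Credible level (default 0.90).
#' @param effect_size Peak deficit in mm (negative; default -0.5).
#' @param config A [spectral_config()] used for every fit (its seed is
#'   advanced per replicate).
#' @param seed Master seed for the simulation stream.
#' @return A tibble with one row per replicate: `replicate`, `coverage`
#'   (share of strong-effect regions whose interval covers the truth),
#'   `coverage_all` (all regions), `n_strong`.
#' @export
recovery_study <- function(nrep = 50, m = 40, level = 0.90,
                           effect_size = -0.5,
                           config = spectral_config(iterations = 2000,
                                                    burnin = 500, thin = 3),
                           seed = 1L) {
  atlas <- make_atlas(1)
  basis <- harmonic_basis(atlas, config$L)
  center <- match("rostralanteriorcingulate_lh", atlas$region)
  xyz <- sphere_to_xyz(atlas)
  d <- sqrt(colSums((t(xyz) - xyz[center, ])^2))
  eff <- sht_inverse(sht_forward(effect_size * exp(-d^2 / (2 * 0.5^2)),
                                 basis), basis)
  strong <- which(eff < effect_size * 0.4)
  truth <- ground_truth(atlas, basis, J = config$J,
                        effects = list(LTLE = eff))
  half <- m %/% 2
  cohort <- withr_seed(seed + 59L, tibble::tibble(
    subject = sprintf("s%03d", seq_len(2 * half)),
    group = factor(rep(c("HC", "LTLE"), each = half),
                   levels = c("HC", "LTLE", "RTLE")),
    age = round(stats::rnorm(2 * half, 30, 7), 1),
    sex = rep_len(c("M", "F"), 2 * half)
  ))
  alpha <- (1 - level) / 2
  purrr::map_dfr(seq_len(nrep), function(rep) {
    ds <- simulate_thickness(atlas, cohort, truth, basis,
                             seed = seed + 1000L + rep)
    cfg <- config
    cfg$seed <- seed + 2000L + rep
    fit <- fit_spectral(ds, cfg)
    dr <- spatial_draws(fit, "LTLE")
    lo <- apply(dr, 2, stats::quantile, alpha)
    hi <- apply(dr, 2, stats::quantile, 1 - alpha)
    covered <- eff >= lo & eff <= hi
    tibble::tibble(replicate = rep, coverage = mean(covered[strong]),
                   coverage_all = mean(covered), n_strong = length(strong))
  })
}

#' Null-data Bayesian-FDR calibration study
#'
#' Simulates cohorts with every covariate effect equal to zero, fits the
#' spectral model, applies the Bayesian FDR rule at rate `q` to the group
#' contrast, and reports the realized false-discovery proportion per
#' replicate (on null data every rejection is false, so the FDP is 1
#' whenever anything is rejected and 0 otherwise) together with the mean
#' posterior z-score.
#'
#' @param nrep Number of replicate cohorts.
#' @param q Target Bayesian FDR.
#' @param covariate Contrast to test (default `"LTLE"`).
#' @param config A [spectral_config()]; seed advanced per replicate.
#' @param seed Master seed.
#' @return A tibble per replicate: `replicate`, `n_rejected`, `fdp`,
#'   `mean_z`.
#' @export
fdr_null_study <- function(nrep = 50, q = 0.01, covariate = "LTLE",
                           config = spectral_config(iterations = 1500,
                                                    burnin = 500, thin = 2),
                           seed = 1L) {
  atlas <- make_atlas(1)
  basis <- harmonic_basis(atlas, config$L)
  truth <- ground_truth(atlas, basis, J = config$J,
                        effects = list(age = 0, sexM = 0, LTLE = 0,
                                       RTLE = 0))
  cohort <- table1_cohort()
  purrr::map_dfr(seq_len(nrep), function(rep) {
    ds <- simulate_thickness(atlas, cohort, truth, basis,
                             seed = seed + 3000L + rep)
    cfg <- config
    cfg$seed <- seed + 4000L + rep
    fit <- fit_spectral(ds, cfg)
    f <- fdr_map(fit, covariate, q = q)
    tibble::tibble(replicate = rep, n_rejected = sum(f$rejected),
                   fdp = as.numeric(sum(f$rejected) > 0),
                   mean_z = mean(f$z))
  })
}
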