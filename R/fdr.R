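#' Posterior null probabilities for one-sided thinning tests
#'
#' For the one-sided hypotheses `H0: B_k(v) >= 0` vs `H1: B_k(v) < 0`, the
#' posterior null probability at a region is the fraction of retained draws
#' of the spatial coefficient surface that are `>= 0`.
#'
#' @param fit A `spectral_fit` with at least 100 retained draws.
#' @param covariate Covariate name (e.g. `"LTLE"`).
#' @return A tibble: `region`, `hemisphere`, `z`, `null_prob`.
#' @export
posterior_null_prob <- function(fit, covariate) {
  stopifnot(inherits(fit, "spectral_fit"))
  if (fit$samples$n_retained < 100L) {
    stop("need at least 100 retained draws for posterior probabilities")
  }
  dr <- spatial_draws(fit, covariate)
  mu <- colMeans(dr); sd <- apply(dr, 2, stats::sd)
  tibble::tibble(region = fit$atlas$region,
                 hemisphere = fit$atlas$hemisphere,
                 z = mu / sd,
                 null_prob = colMeans(dr >= 0))
}

#' Bayesian false-discovery-rate threshold
#'
#' Controls the Bayesian FDR at rate `q` by the posterior-probability
#' rule: sort the posterior null probabilities ascending and reject the
#' largest prefix whose running mean stays `<= q` — the expected proportion
#' of true nulls among the rejections is then at most `q`. The implied
#' z-score threshold reported is the largest posterior z among the rejected
#' regions.
#'
#' @param null_probs Either the tibble from [posterior_null_prob()] or a
#'   bare numeric vector of posterior null probabilities.
#' @param q Target Bayesian FDR, in `(0, 1]` (default 0.01).
#' @return An object of class `fdr_result`: the input table with a
#'   `rejected` flag, plus attributes `q` and `z_threshold`. `tidy()`
#'   returns the table; `glance()` the rejection count and threshold.
#' @export
bayesian_fdr <- function(null_probs, q = 0.01) {
  if (q <= 0 || q > 1) stop("q must be in (0, 1]")
  if (is.numeric(null_probs)) {
    null_probs <- tibble::tibble(region = as.character(seq_along(null_probs)),
                                 hemisphere = NA_character_,
                                 z = NA_real_, null_prob = null_probs)
  }
  tab <- null_probs
  if (nrow(tab) == 0L) stop("no hypotheses supplied")
  if (any(tab$null_prob < 0 | tab$null_prob > 1)) {
    stop("posterior null probabilities must lie in [0, 1]")
  }
  ord <- order(tab$null_prob)
  run_mean <- cumsum(tab$null_prob[ord]) / seq_along(ord)
  n_rej <- if (any(run_mean <= q)) max(which(run_mean <= q)) else 0L
  rejected <- logical(nrow(tab))
  rejected[ord[seq_len(n_rej)]] <- TRUE
  tab$rejected <- rejected
  zthr <- if (n_rej > 0L && !all(is.na(tab$z))) {
    max(tab$z[rejected], na.rm = TRUE)
  } else NA_real_
  structure(tab, class = c("fdr_result", class(tab)),
            q = q, z_threshold = zthr)
}

#' @export
print.fdr_result <- function(x, ...) {
  cat("<fdr_result> q =", attr(x, "q"), "|", sum(x$rejected), "of",
      nrow(x), "regions rejected; z threshold",
      format(attr(x, "z_threshold"), digits = 3), "\n")
  NextMethod()
}

#' @rdname bayesian_fdr
#' @param x An `fdr_result`.
#' @param ... Unused.
#' @export
tidy.fdr_result <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' @rdname bayesian_fdr
#' @export
glance.fdr_result <- function(x, ...) {
  tibble::tibble(q = attr(x, "q"), n_regions = nrow(x),
                 n_rejected = sum(x$rejected),
                 z_threshold = attr(x, "z_threshold"))
}

#' Significance report for a group contrast
#'
#' Convenience wrapper: posterior null probabilities for a covariate,
#' thresholded at Bayesian FDR `q`, shaped like a regional thinning table
#' (region, hemisphere, z-score, null probability, rejected flag).
#'
#' @inheritParams posterior_null_prob
#' @inheritParams bayesian_fdr
#' @return An `fdr_result`.
#' @export
fdr_map <- function(fit, covariate, q = 0.01) {
  bayesian_fdr(posterior_null_prob(fit, covariate), q = q)
}
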