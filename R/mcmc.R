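# MCMC engine for the spectral hierarchical model.
#
# Data model, per spectral column w (frequency) and subject i:
#   Ytil[i, w] ~ N( sum_k X[i, k] B[k, w] + gamma[i, j] 1[w = j-th window col],
#                   lamE[w] )
# with priors
#   B[k, w]  ~ N( beta[k, j] 1[w in window], lamB0[w] (k = intercept)
#                                             / lamB1[w] (k > intercept) )
#   gamma_i  ~ N(0, Sigma),  Sigma ~ InvWishart(J + eps, nu3/(J + eps) I)
#   beta_0j  ~ N(0, delta0^2);  beta_kj ~ N(0, delta_kj^2) with gaussian or
#   horseshoe (half-Cauchy local scale) structure on delta_kj.
# Spectral variances lamE/lamB0/lamB1 are flat in degree ("independent") or
# follow the Matern spectral density in the total-variance/logit-proportion/
# log-range/log-smoothness parameterization, with conjugate updates for the
# total variance and random-walk Metropolis for the rest.

rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape, rate = rate)

# One spectral-variance block. ss_deg / cnt_deg are per-degree residual sums
# of squares and term counts; the block holds (v, r, log_phi, log_nu).
new_var_block <- function(structure, eps, deg_levels, fixed_var = NULL,
                          v0 = 1) {
  blk <- list(structure = structure, eps = eps, deg_levels = deg_levels,
              v = v0, r = 0, log_phi = 0, log_nu = -2,
              step = 0.3, acc = 0L, tries = 0L,
              fixed = !is.null(fixed_var))
  if (blk$fixed) {
    blk$lam_deg <- rep_len(fixed_var, length(deg_levels))
  } else {
    blk$lam_deg <- blk$v * block_shape(blk)
  }
  blk
}

block_shape <- function(blk) {
  if (blk$structure == "independent") return(rep(1, length(blk$deg_levels)))
  p <- stats::plogis(blk$r)
  (1 - p) + p * spectral_shape(blk$deg_levels, exp(blk$log_phi),
                               exp(blk$log_nu))
}

block_logprior <- function(r, log_phi, log_nu, eps) {
  stats::dnorm(r, 0, 1, log = TRUE) +
    stats::dnorm(log_phi, 0, 1 / eps, log = TRUE) +
    stats::dnorm(log_nu, -2, 1, log = TRUE)
}

block_loglik <- function(v, h, ss_deg, cnt_deg) {
  if (any(!is.finite(h)) || any(h <= 0) || v <= 0) return(-Inf)
  sum(-0.5 * cnt_deg * log(v * h) - ss_deg / (2 * v * h))
}

# Conjugate total-variance draw then joint RW-Metropolis on the shape
# parameters; step adapted toward 25-45% acceptance while `adapt` is TRUE.
update_var_block <- function(blk, ss_deg, cnt_deg, adapt) {
  if (blk$fixed) return(blk)
  h <- block_shape(blk)
  blk$v <- rinvgamma(1, blk$eps + sum(cnt_deg) / 2,
                     blk$eps + 0.5 * sum(ss_deg / h))
  if (!is.finite(blk$v) || blk$v <= 0) blk$v <- 1e-8
  if (blk$structure == "matern") {
    prop <- c(blk$r, blk$log_phi, blk$log_nu) + blk$step * stats::rnorm(3)
    blk2 <- blk; blk2$r <- prop[1]; blk2$log_phi <- prop[2]
    blk2$log_nu <- prop[3]
    h2 <- block_shape(blk2)
    logacc <- block_loglik(blk$v, h2, ss_deg, cnt_deg) +
      block_logprior(prop[1], prop[2], prop[3], blk$eps) -
      block_loglik(blk$v, h, ss_deg, cnt_deg) -
      block_logprior(blk$r, blk$log_phi, blk$log_nu, blk$eps)
    blk$tries <- blk$tries + 1L
    if (is.finite(logacc) && log(stats::runif(1)) < logacc) {
      blk$r <- prop[1]; blk$log_phi <- prop[2]; blk$log_nu <- prop[3]
      blk$acc <- blk$acc + 1L
    }
    if (adapt && blk$tries %% 50L == 0L) {
      rate <- blk$acc / blk$tries
      if (rate > 0.45) blk$step <- blk$step * 1.3
      if (rate < 0.25) blk$step <- blk$step / 1.3
      blk$acc <- 0L; blk$tries <- 0L
    }
  }
  blk$lam_deg <- blk$v * block_shape(blk)
  blk
}

#' Run the spectral-domain MCMC sampler
#'
#' Fits the hierarchical spectral model by Markov chain Monte Carlo:
#' conjugate Gibbs updates for the spectral fixed effects, basis
#' coefficients, random effects, their covariance and all variance scales,
#' and random-walk Metropolis for the Matern shape parameters of each
#' variance block (step sizes adapted during burn-in only). Deterministic
#' given the seed.
#'
#' @param spectral Subjects x frequencies matrix of spectral coefficients
#'   (from [transform_dataset()]).
#' @param X Subjects x covariates design matrix including an intercept
#'   column (first).
#' @param degrees Integer vector: the harmonic degree of each spectral
#'   column.
#' @param config A [spectral_config()].
#' @return A list of class `spectral_samples`: `B` (draws x covariates x
#'   frequencies array), `beta`, `Sigma`, `theta` (tibble of variance-block
#'   draws), `accept`, `n_retained`, plus the config and dimension labels.
#' @export
run_mcmc <- function(spectral, X, degrees, config) {
  stopifnot(inherits(config, "spectral_config"))
  spectral <- as.matrix(spectral); X <- as.matrix(X)
  m <- nrow(spectral); K <- ncol(spectral); P <- ncol(X)
  if (nrow(X) != m) stop("design matrix rows must match subjects")
  if (length(degrees) != K) stop("need one degree per spectral column")
  if (any(!is.finite(spectral)) || any(!is.finite(X))) {
    stop("non-finite values in the spectral data or design")
  }
  if (config$J > K) stop("J exceeds the spectral dimension")
  eps <- config$epsilon
  J <- config$J
  Lset <- seq_len(J)
  covnames <- colnames(X)
  if (is.null(covnames)) covnames <- paste0("x", seq_len(P) - 1L)

  deg_levels <- sort(unique(degrees))
  deg_id <- match(degrees, deg_levels)
  cols_by_deg <- split(seq_len(K), deg_id)
  n_deg <- lengths(cols_by_deg)

  XtX <- crossprod(X)
  nret <- (config$iterations - config$burnin) %/% config$thin

  fx <- config$fixed
  withr_seed(config$seed, {
    # --- initial state ---------------------------------------------------
    B <- tryCatch(solve(XtX + diag(1e-8, P), crossprod(X, spectral)),
                  error = function(e) matrix(0, P, K))
    resid0 <- spectral - X %*% B
    v_init <- max(stats::var(as.vector(resid0)), 1e-6)
    blkE <- new_var_block(config$residual, eps, deg_levels, fx$resid_var,
                          v0 = v_init)
    blk0 <- new_var_block(config$residual, eps, deg_levels, fx$b0_var,
                          v0 = max(stats::var(B[1, ]), 1e-6))
    blk1 <- if (P > 1L) {
      new_var_block(config$residual, eps, deg_levels, fx$b_var,
                    v0 = max(stats::var(as.vector(B[-1, , drop = FALSE])),
                             1e-6))
    } else NULL

    beta <- matrix(0, P, J)
    delta0sq <- if (is.null(fx$delta0_var)) 1 else fx$delta0_var
    fix_delta <- !is.null(fx$delta_var)
    deltaksq <- rep(if (fix_delta) fx$delta_var else 1, max(P - 1L, 1L))
    hs_local <- matrix(1, max(P - 1L, 1L), J)   # horseshoe local variances
    hs_aux <- matrix(1, max(P - 1L, 1L), J)
    hs_global <- rep(1, max(P - 1L, 1L))

    Gamma <- matrix(0, m, J)
    Sigma <- diag(0.01, J)
    nu3 <- 1
    nu3_step <- 0.5; nu3_acc <- 0L; nu3_tries <- 0L
    jitter_events <- 0L

    draw_B <- array(NA_real_, c(nret, P, K),
                    dimnames = list(NULL, covnames, colnames(spectral)))
    draw_beta <- array(NA_real_, c(nret, P, J),
                       dimnames = list(NULL, covnames, NULL))
    draw_Sigma <- if (config$nonstationary) array(NA_real_, c(nret, J, J)) else NULL
    draw_theta <- vector("list", nret)

    lam_cols <- function(blk) blk$lam_deg[deg_id]

    for (it in seq_len(config$iterations)) {
      adapt <- it <= config$burnin
      lamE <- lam_cols(blkE)
      lam0 <- lam_cols(blk0)
      lam1 <- if (P > 1L) lam_cols(blk1) else NULL

      # residual with the gamma term removed: likelihood data for B
      R <- spectral
      if (config$nonstationary) R[, Lset] <- R[, Lset] - Gamma
      XtR <- crossprod(X, R)

      mu0 <- matrix(0, P, K)
      mu0[, Lset] <- beta

      # --- B: per-degree joint conjugate update --------------------------
      for (g in seq_along(cols_by_deg)) {
        cols <- cols_by_deg[[g]]
        Dinv <- c(1 / blk0$lam_deg[g],
                  if (P > 1L) rep(1 / blk1$lam_deg[g], P - 1L))
        A <- XtX / blkE$lam_deg[g] + diag(Dinv, P)
        U <- chol(A)
        rhs <- XtR[, cols, drop = FALSE] / blkE$lam_deg[g] +
          mu0[, cols, drop = FALSE] * Dinv
        mean_g <- backsolve(U, backsolve(U, rhs, transpose = TRUE))
        B[, cols] <- mean_g +
          backsolve(U, matrix(stats::rnorm(P * length(cols)), P))
      }

      # --- beta and its scales ------------------------------------------
      prior_var <- rbind(delta0sq,
                         if (P > 1L) {
                           if (config$fe_prior == "horseshoe") hs_local
                           else matrix(deltaksq, P - 1L, J)
                         })
      lam_rows <- rbind(lam0[Lset],
                        if (P > 1L) matrix(lam1[Lset], P - 1L, J,
                                           byrow = TRUE))
      post_var <- 1 / (1 / lam_rows + 1 / prior_var)
      post_mean <- post_var * B[, Lset, drop = FALSE] / lam_rows
      beta <- post_mean + sqrt(post_var) * stats::rnorm(P * J)
      dim(beta) <- c(P, J)

      if (is.null(fx$delta0_var)) {
        delta0sq <- rinvgamma(1, eps + J / 2, eps + sum(beta[1, ]^2) / 2)
      }
      if (P > 1L && !fix_delta) {
        bsl <- beta[-1, , drop = FALSE]
        if (config$fe_prior == "gaussian") {
          deltaksq <- rinvgamma(P - 1L, eps + J / 2,
                                eps + rowSums(bsl^2) / 2)
        } else {
          hs_local <- matrix(rinvgamma(length(bsl), 1,
                                       1 / hs_aux + bsl^2 / 2),
                             P - 1L, J)
          hs_aux <- matrix(rinvgamma(length(bsl), 1,
                                     1 / hs_global + 1 / hs_local),
                           P - 1L, J)
          hs_global <- rinvgamma(P - 1L, eps + J / 2,
                                 eps + rowSums(1 / hs_aux))
        }
      }

      # --- random effects ------------------------------------------------
      if (config$nonstationary) {
        Rg <- spectral[, Lset, drop = FALSE] - (X %*% B[, Lset, drop = FALSE])
        Sinv <- tryCatch(chol2inv(chol(Sigma)), error = function(e) {
          jitter_events <<- jitter_events + 1L
          chol2inv(chol(Sigma + diag(1e-8, J)))
        })
        Q <- Sinv + diag(1 / lamE[Lset], J)
        Uq <- chol(Q)
        bmat <- t(Rg) / lamE[Lset]           # J x m
        mean_g <- backsolve(Uq, backsolve(Uq, bmat, transpose = TRUE))
        Gamma <- t(mean_g + backsolve(Uq, matrix(stats::rnorm(J * m), J)))

        Sc <- diag(nu3 / (J + eps), J) + crossprod(Gamma)
        df <- J + eps + m
        W <- tryCatch(
          stats::rWishart(1, df, chol2inv(chol(Sc)))[, , 1],
          error = function(e) {
            jitter_events <<- jitter_events + 1L
            stats::rWishart(1, df,
                            chol2inv(chol(Sc + diag(1e-8, J))))[, , 1]
          })
        Sigma <- chol2inv(chol(W + diag(1e-10, J)))

        # nu3: log-scale random walk on its InvWishart+InvGamma conditional
        tr_si <- sum(diag(chol2inv(chol(Sigma + diag(1e-10, J)))))
        log_target <- function(lx) {
          x <- exp(lx)
          ((J + eps) * J / 2) * lx - 0.5 * (x / (J + eps)) * tr_si +
            (-eps - 1) * lx - eps / x + lx   # last lx: log-scale Jacobian
        }
        lprop <- log(nu3) + nu3_step * stats::rnorm(1)
        nu3_tries <- nu3_tries + 1L
        if (log(stats::runif(1)) < log_target(lprop) - log_target(log(nu3))) {
          nu3 <- exp(lprop); nu3_acc <- nu3_acc + 1L
        }
        if (adapt && nu3_tries %% 50L == 0L) {
          rate <- nu3_acc / nu3_tries
          if (rate > 0.45) nu3_step <- nu3_step * 1.3
          if (rate < 0.25) nu3_step <- nu3_step / 1.3
          nu3_acc <- 0L; nu3_tries <- 0L
        }
      }

      # --- variance blocks ----------------------------------------------
      Rfull <- spectral - X %*% B
      if (config$nonstationary) {
        Rfull[, Lset] <- Rfull[, Lset] - Gamma
      }
      ssE_col <- colSums(Rfull^2)
      ssE_deg <- vapply(cols_by_deg, function(cc) sum(ssE_col[cc]), 0)
      blkE <- update_var_block(blkE, ssE_deg, m * n_deg, adapt)

      dev0 <- B[1, ] - mu0[1, ]
      ss0_deg <- vapply(cols_by_deg, function(cc) sum(dev0[cc]^2), 0)
      blk0 <- update_var_block(blk0, ss0_deg, n_deg, adapt)

      if (P > 1L) {
        dev1 <- B[-1, , drop = FALSE] - mu0[-1, , drop = FALSE]
        ss1_col <- colSums(dev1^2)
        ss1_deg <- vapply(cols_by_deg, function(cc) sum(ss1_col[cc]), 0)
        blk1 <- update_var_block(blk1, ss1_deg, (P - 1L) * n_deg, adapt)
      }

      # --- retain --------------------------------------------------------
      if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
        s <- (it - config$burnin) %/% config$thin
        draw_B[s, , ] <- B
        draw_beta[s, , ] <- beta
        if (config$nonstationary) draw_Sigma[s, , ] <- Sigma
        draw_theta[[s]] <- tibble::tibble(
          block = c("residual", "intercept", if (P > 1L) "slope"),
          v = c(blkE$v, blk0$v, if (P > 1L) blk1$v),
          r = c(blkE$r, blk0$r, if (P > 1L) blk1$r),
          log_phi = c(blkE$log_phi, blk0$log_phi, if (P > 1L) blk1$log_phi),
          log_nu = c(blkE$log_nu, blk0$log_nu, if (P > 1L) blk1$log_nu),
          nu3 = nu3
        )
      }
    }

    theta <- dplyr::bind_rows(draw_theta, .id = "draw")
    theta$draw <- as.integer(theta$draw)
    structure(list(
      B = draw_B, beta = draw_beta, Sigma = draw_Sigma, theta = theta,
      n_retained = nret,
      accept = list(
        residual = if (blkE$tries > 0) blkE$acc / blkE$tries else NA_real_,
        intercept = if (blk0$tries > 0) blk0$acc / blk0$tries else NA_real_,
        slope = if (P > 1L && blk1$tries > 0) blk1$acc / blk1$tries else NA_real_,
        nu3 = if (nu3_tries > 0) nu3_acc / nu3_tries else NA_real_
      ),
      jitter_events = jitter_events,
      covariates = covnames, degrees = degrees, config = config
    ), class = "spectral_samples")
  })
}
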