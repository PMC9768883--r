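#' Thickness dataset container
#'
#' Bundles a subjects x regions thickness matrix (mm) with its cohort table
#' and region atlas, checking that labels align and values are finite and
#' positive.
#'
#' @param thickness Numeric matrix, rows named by subject, columns by region.
#' @param cohort Cohort tibble (`subject`, `group`, `age`, `sex`).
#' @param atlas Atlas tibble from [make_atlas()] or [read_atlas()].
#' @return An object of class `thickness_dataset`.
#' @export
thickness_dataset <- function(thickness, cohort, atlas) {
  validate_cohort(cohort)
  validate_atlas(atlas)
  thickness <- as.matrix(thickness)
  if (is.null(rownames(thickness)) || is.null(colnames(thickness))) {
    stop("thickness matrix must carry subject row names and region column names")
  }
  if (!setequal(rownames(thickness), cohort$subject)) {
    stop("thickness rows and cohort subjects do not match")
  }
  if (!setequal(colnames(thickness), atlas$region)) {
    stop("thickness columns and atlas regions do not match")
  }
  thickness <- thickness[cohort$subject, atlas$region, drop = FALSE]
  if (any(is.na(thickness))) {
    bad <- which(is.na(thickness), arr.ind = TRUE)[1, ]
    stop("missing thickness value at subject ", rownames(thickness)[bad[1]],
         ", region ", colnames(thickness)[bad[2]])
  }
  if (any(!is.finite(thickness))) stop("thickness values must be finite")
  if (any(thickness <= 0)) stop("thickness values must be positive (mm)")
  structure(list(thickness = thickness, cohort = cohort, atlas = atlas),
            class = "thickness_dataset")
}

#' @export
print.thickness_dataset <- function(x, ...) {
  cat("<thickness_dataset>", nrow(x$thickness), "subjects x",
      ncol(x$thickness), "regions; groups:",
      paste(levels(factor(x$cohort$group)), table(x$cohort$group),
            sep = "=", collapse = " "), "\n")
  invisible(x)
}

# Design matrix: intercept, centered age, sex (M=1), LTLE and RTLE dummies
# with HC as the baseline group. `center` lets prediction reuse the
# training-sample age center.
design_matrix <- function(cohort, center = NULL) {
  if (is.null(center)) center <- mean(cohort$age)
  X <- cbind(
    intercept = 1,
    age = cohort$age - center,
    sexM = as.numeric(cohort$sex == "M"),
    LTLE = as.numeric(cohort$group == "LTLE"),
    RTLE = as.numeric(cohort$group == "RTLE")
  )
  attr(X, "age_center") <- center
  X
}

#' Ground truth for the synthetic cohort generator
#'
#' Defines the generating model for synthetic thickness data: a smooth
#' baseline surface around 2.7 mm, spatially varying covariate effect
#' surfaces (mm per covariate unit), a random-effect covariance `Sigma`
#' (J x J) on the leading harmonic basis columns, and Matern residual
#' parameters. Defaults emulate the magnitudes seen in regional
#' thickness tables: group deficits of 0.1-0.2 mm in focal clusters,
#' residual spread ~0.17 mm, a mild subject-level offset.
#'
#' @param atlas Region atlas tibble.
#' @param basis A `harmonic_basis` evaluated at the atlas centroids.
#' @param J Number of nonstationary basis columns (default 9).
#' @param effects Named list of per-region effect surfaces; any of `age`,
#'   `sexM`, `LTLE`, `RTLE` may be given as a single number applied to the
#'   regions in `effect_regions`, or as a full per-region vector. Defaults:
#'   LTLE -0.15 mm on cingulate/frontal regions, RTLE -0.10 mm on right
#'   entorhinal, age -0.005 mm/year everywhere, sex 0.
#' @param effect_regions Named list of character vectors of region names the
#'   scalar effects act on.
#' @param Sigma Random-effect covariance (J x J, symmetric positive
#'   semi-definite; all-zero switches the random effects off), default
#'   `0.004 * I`.
#' @param residual A `matern_params` for the residual process, or `NULL`
#'   for a noise-free generator (exactness checks).
#' @param seed Integer seed used for the baseline surface shape and carried
#'   as the default simulation seed.
#' @return A list of class `ground_truth` with `baseline`, `B` (covariates x
#'   regions matrix over age/sexM/LTLE/RTLE), `Sigma`, `residual`, `J`,
#'   `seed`.
#' @export
ground_truth <- function(atlas, basis, J = 9L,
                         effects = list(), effect_regions = list(),
                         Sigma = NULL,
                         residual = matern_params(0.01, 0.02, 0.5, 1),
                         seed = 1L) {
  stopifnot(inherits(basis, "harmonic_basis"))
  n <- nrow(atlas)
  J <- as.integer(J)
  if (J < 1L || J > ncol(basis$matrix)) stop("J out of range for the basis")
  if (is.null(Sigma)) Sigma <- diag(0.004, J)
  Sigma <- as.matrix(Sigma)
  if (!isSymmetric(Sigma, tol = 1e-8) ||
      min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("Sigma must be symmetric positive semi-definite")
  }
  default_regions <- list(
    LTLE = grep("cingulate|frontal", atlas$region, value = TRUE),
    RTLE = "entorhinal_rh"
  )
  effect_regions <- utils::modifyList(default_regions, effect_regions)
  defaults <- list(age = -0.005, sexM = 0, LTLE = -0.15, RTLE = -0.10)
  effects <- utils::modifyList(defaults, effects)
  B <- matrix(0, 4, n, dimnames = list(c("age", "sexM", "LTLE", "RTLE"),
                                       atlas$region))
  for (k in rownames(B)) {
    ek <- effects[[k]]
    if (length(ek) == n) {
      B[k, ] <- ek
    } else if (length(ek) == 1L) {
      regs <- effect_regions[[k]]
      if (is.null(regs)) {
        B[k, ] <- ek
      } else {
        B[k, match(regs, atlas$region)] <- ek
      }
    } else {
      stop("effect '", k, "' must be scalar or one value per region")
    }
  }
  baseline <- withr_seed(seed + 977L, {
    ncoef <- min(9L, ncol(basis$matrix))
    co <- numeric(ncol(basis$matrix))
    co[seq_len(ncoef)] <- stats::rnorm(ncoef, 0, 0.12)
    co[1] <- 0
    2.7 + sht_inverse(co, basis)
  })
  structure(list(baseline = baseline, B = B, Sigma = Sigma,
                 residual = residual, J = J, seed = as.integer(seed)),
            class = "ground_truth")
}

#' Simulate a synthetic thickness dataset
#'
#' Draws subjects x regions thickness values from the generating model:
#' baseline surface plus covariate effects `X_ik * B_k(v)`, plus
#' nonstationary random effects `sum_j Z_j(v) gamma_ij` with
#' `gamma_i ~ N(0, Sigma)` on the first `J` harmonic basis columns, plus a
#' Matern-correlated residual field per subject. Deterministic given the
#' seed.
#'
#' @param atlas Region atlas tibble.
#' @param cohort Cohort tibble.
#' @param truth A [ground_truth()] object.
#' @param basis The `harmonic_basis` at the atlas centroids.
#' @param seed Integer seed; defaults to `truth$seed`.
#' @return A `thickness_dataset`; the truth used is attached as attribute
#'   `"truth"` and the design-matrix age center as `"age_center"`.
#' @export
simulate_thickness <- function(atlas, cohort, truth, basis,
                               seed = truth$seed) {
  stopifnot(inherits(truth, "ground_truth"), inherits(basis, "harmonic_basis"))
  validate_cohort(cohort)
  n <- nrow(atlas)
  m <- nrow(cohort)
  if (length(truth$baseline) != n || ncol(truth$B) != n) {
    stop("ground truth dimensions do not match the atlas")
  }
  if (nrow(basis$matrix) != n) stop("basis points do not match the atlas")
  J <- truth$J
  X <- design_matrix(cohort)
  Ball <- rbind(intercept = truth$baseline, truth$B)
  fixed <- X %*% Ball
  Z <- basis$matrix[, frequency_set(J, basis), drop = FALSE]
  Rchol <- if (is.null(truth$residual)) NULL else {
    chol(matern_covariance(atlas, truth$residual) + diag(1e-10, n))
  }
  Schol <- if (all(truth$Sigma == 0)) NULL else {
    chol(truth$Sigma + diag(1e-12, J))
  }
  Y <- withr_seed(seed, {
    gamma <- if (is.null(Schol)) matrix(0, m, J) else {
      matrix(stats::rnorm(m * J), m, J) %*% Schol
    }
    E <- if (is.null(Rchol)) matrix(0, m, n) else {
      matrix(stats::rnorm(m * n), m, n) %*% Rchol
    }
    fixed + gamma %*% t(Z) + E
  })
  dimnames(Y) <- list(cohort$subject, atlas$region)
  ds <- thickness_dataset(Y, cohort, atlas)
  attr(ds, "truth") <- truth
  attr(ds, "age_center") <- attr(X, "age_center")
  ds
}

#' Write / read a thickness dataset as delimited text
#'
#' Persists a dataset as three tab-separated files in `dir`:
#' `thickness.tsv` (first column `subject`, then one column per region),
#' `cohort.tsv` and `atlas.tsv`.
#'
#' @param ds A `thickness_dataset`.
#' @param dir Output directory (created if missing).
#' @return `write_dataset()` returns the directory, invisibly;
#'   `load_inputs()` (see [load_inputs()]) reads the files back.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "thickness_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  th <- tibble::as_tibble(ds$thickness, rownames = "subject")
  readr::write_tsv(th, file.path(dir, "thickness.tsv"))
  readr::write_tsv(ds$cohort, file.path(dir, "cohort.tsv"))
  write_atlas(ds$atlas, file.path(dir, "atlas.tsv"))
  invisible(dir)
}
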