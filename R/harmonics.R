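#' Associated Legendre function P_l^m(x)
#'
#' Evaluates the associated Legendre function of the first kind with the
#' Condon--Shortley phase, i.e. `P_l^m(x) = (-1)^m (1-x^2)^{m/2} d^m/dx^m P_l(x)`
#' for `m >= 0`. Computed by the standard stable upward recurrence in the
#' degree from the closed-form diagonal term `P_m^m`.
#'
#' @param l Degree, a single integer `>= 0`.
#' @param m Order, a single integer with `0 <= m <= l`.
#' @param x Evaluation points in `[-1, 1]` (vectorized).
#' @return A numeric vector, `P_l^m(x)` at each point.
#' @examples
#' assoc_legendre(2, 0, 1)       # (3x^2 - 1)/2 at x = 1 -> 1
#' assoc_legendre(1, 1, 0)       # -sqrt(1 - x^2) -> -1
#' @export
assoc_legendre <- function(l, m, x) {
  stopifnot(length(l) == 1L, length(m) == 1L)
  l <- as.integer(l); m <- as.integer(m)
  if (l < 0L || m < 0L || m > l) {
    stop("assoc_legendre requires 0 <= m <= l, got l=", l, ", m=", m)
  }
  if (any(!is.finite(x)) || any(abs(x) > 1 + 1e-12)) {
    stop("assoc_legendre requires x in [-1, 1]")
  }
  x <- pmin(1, pmax(-1, x))
  # diagonal start: P_m^m = (-1)^m (2m-1)!! (1-x^2)^{m/2}
  pmm <- rep(1, length(x))
  if (m > 0L) {
    somx2 <- sqrt((1 - x) * (1 + x))
    fact <- 1
    for (i in seq_len(m)) {
      pmm <- -pmm * fact * somx2
      fact <- fact + 2
    }
  }
  if (l == m) return(pmm)
  pmmp1 <- x * (2 * m + 1) * pmm               # P_{m+1}^m
  if (l == m + 1L) return(pmmp1)
  for (ll in seq.int(m + 2L, l)) {
    pll <- (x * (2 * ll - 1) * pmmp1 - (ll + m - 1) * pmm) / (ll - m)
    pmm <- pmmp1
    pmmp1 <- pll
  }
  pmmp1
}

#' Spherical points
#'
#' Constructs a tibble of points on the unit sphere from colatitude and
#' longitude in radians. Colatitude must lie in `[0, pi]`; longitude is
#' wrapped into `[0, 2*pi)`.
#'
#' @param colatitude Colatitude in radians, `[0, pi]` (0 = north pole).
#' @param longitude Longitude in radians; wrapped into `[0, 2*pi)`.
#' @return A tibble with columns `colatitude`, `longitude`.
#' @export
sphere_points <- function(colatitude, longitude) {
  stopifnot(length(colatitude) == length(longitude))
  if (any(!is.finite(colatitude)) || any(!is.finite(longitude))) {
    stop("sphere_points requires finite angles")
  }
  if (any(colatitude < -1e-12 | colatitude > pi + 1e-12)) {
    stop("colatitude must lie in [0, pi]")
  }
  tibble::tibble(
    colatitude = pmin(pi, pmax(0, colatitude)),
    longitude = longitude %% (2 * pi)
  )
}

# Unit 3-vectors for rows of a sphere_points tibble.
sphere_to_xyz <- function(points) {
  s1 <- points$colatitude
  s2 <- points$longitude
  cbind(
    x = sin(s1) * cos(s2),
    y = sin(s1) * sin(s2),
    z = cos(s1)
  )
}

#' Unnormalized complex spherical harmonic S_l^m
#'
#' Evaluates `S_l^m(s1, s2) = P_l^m(cos s1) * exp(-i m s2)` at spherical
#' points, with `P_l^m` carrying the Condon--Shortley phase and negative
#' orders defined through `P_l^{-m} = (-1)^m (l-m)!/(l+m)! P_l^m`.
#'
#' @param l Degree (integer `>= 0`).
#' @param m Order (integer, `|m| <= l`).
#' @param points A `sphere_points()` tibble.
#' @return A complex vector, one value per point.
#' @export
spherical_harmonic <- function(l, m, points) {
  l <- as.integer(l); m <- as.integer(m)
  if (abs(m) > l) stop("spherical_harmonic requires |m| <= l")
  am <- abs(m)
  p <- assoc_legendre(l, am, cos(points$colatitude))
  if (m < 0L) {
    p <- p * (-1)^am * exp(lgamma(l - am + 1) - lgamma(l + am + 1))
  }
  p * exp(complex(imaginary = -m * points$longitude))
}

#' Real spherical-harmonic basis at scattered points
#'
#' Builds the real-valued harmonic design matrix used to move regional data
#' between the spatial and spectral domains. For each degree `l <= L` the
#' `m = 0` harmonic contributes one real column and each `m > 0` harmonic two
#' columns (`sqrt(2)` times its real and imaginary parts), so a real field's
#' representation keeps one value per frequency; every column is scaled by
#' `1/sqrt(2l + 1)` and Schmidt semi-normalized by `sqrt((l-m)!/(l+m)!)`.
#' The semi-normalization puts all orders of a degree on a common scale —
#' without it the raw associated Legendre functions grow like `(l+m)!` and a
#' degree-only spectral variance has no meaning. The total is `(L+1)^2`
#' columns, ordered by increasing degree, then increasing order, real part
#' before imaginary.
#'
#' @param points A `sphere_points()` tibble (or a region atlas with
#'   `colatitude`/`longitude` columns); at least one row.
#' @param L Maximum harmonic degree, integer `>= 0`.
#' @return An object of class `harmonic_basis`: a list with `L`, `index`
#'   (tibble of `l`, `m`, `part`, `column`), the evaluation `matrix`
#'   (points x columns) and the `points` tibble.
#' @examples
#' b <- harmonic_basis(sphere_points(c(0.3, 1.2, 2.0), c(0, 2, 4)), L = 1)
#' dim(b$matrix)  # 3 x 4
#' @export
harmonic_basis <- function(points, L) {
  stopifnot(length(L) == 1L, L >= 0)
  L <- as.integer(L)
  if (is.null(points$colatitude) || nrow(points) == 0L) {
    stop("harmonic_basis requires at least one spherical point")
  }
  idx <- harmonic_index(L)
  cols <- vector("list", nrow(idx))
  for (j in seq_len(nrow(idx))) {
    l <- idx$l[j]; m <- idx$m[j]
    schmidt <- sqrt(exp(lgamma(l - m + 1) - lgamma(l + m + 1)))
    s <- spherical_harmonic(l, m, points) * schmidt / sqrt(2 * l + 1)
    cols[[j]] <- switch(idx$part[j],
      re0 = Re(s),
      re  = sqrt(2) * Re(s),
      im  = sqrt(2) * Im(s)
    )
  }
  mat <- do.call(cbind, cols)
  colnames(mat) <- idx$label
  structure(
    list(L = L, index = idx, matrix = mat, points = points),
    class = "harmonic_basis"
  )
}

# Deterministic real-representation column index for max degree L:
# l ascending, m ascending, Re before Im for m > 0.
harmonic_index <- function(L) {
  rows <- list()
  for (l in 0:L) {
    rows[[length(rows) + 1L]] <- tibble::tibble(l = l, m = 0L, part = "re0")
    if (l > 0L) {
      for (m in seq_len(l)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(l = l, m = m, part = "re")
        rows[[length(rows) + 1L]] <- tibble::tibble(l = l, m = m, part = "im")
      }
    }
  }
  idx <- dplyr::bind_rows(rows)
  idx$column <- seq_len(nrow(idx))
  idx$label <- paste0("l", idx$l, "m", idx$m, "_", idx$part)
  idx
}

#' @export
print.harmonic_basis <- function(x, ...) {
  cat("<harmonic_basis> L =", x$L, "|", nrow(x$matrix), "points x",
      ncol(x$matrix), "real columns\n")
  invisible(x)
}

#' Forward spherical-harmonic transform (scattered points)
#'
#' Projects one real value per point (or the rows of a matrix) onto the
#' real harmonic basis by least squares, solved through a QR factorization
#' for numerical stability on the moderately ill-conditioned systems that
#' scattered centroids produce. If the evaluation matrix is rank-deficient
#' (e.g. fewer points than columns) the solve falls back to the
#' minimum-norm least-squares solution via the SVD pseudo-inverse, so
#' degenerate point sets still return a deterministic coefficient vector
#' and consistent systems reconstruct exactly.
#'
#' @param values Numeric vector, one value per basis point (or a
#'   fields x points matrix for several fields at once).
#' @param basis A `harmonic_basis`.
#' @return Numeric coefficient vector of length `(L+1)^2`, named by column
#'   (or a fields x `(L+1)^2` matrix).
#' @export
sht_forward <- function(values, basis) {
  stopifnot(inherits(basis, "harmonic_basis"))
  S <- basis$matrix
  vec <- is.null(dim(values))
  V <- if (vec) matrix(values, ncol = 1) else t(values)
  if (nrow(V) != nrow(S)) {
    stop("sht_forward: got ", nrow(V), " values for ", nrow(S), " points")
  }
  if (any(!is.finite(V))) stop("sht_forward: non-finite values")
  qrS <- qr(S)
  if (qrS$rank == ncol(S)) {
    coef <- qr.coef(qrS, V)
  } else {
    # rank-deficient (fewer points than columns, or degenerate layout):
    # minimum-norm least squares via the pseudo-inverse, which is exact on
    # consistent systems
    sv <- svd(S)
    tol <- max(dim(S)) * .Machine$double.eps * sv$d[1]
    keep <- sv$d > tol
    coef <- sv$v[, keep, drop = FALSE] %*%
      ((crossprod(sv$u[, keep, drop = FALSE], V)) / sv$d[keep])
  }
  if (vec) {
    coef <- drop(coef)
    names(coef) <- colnames(S)
    coef
  } else {
    coef <- t(coef)
    dimnames(coef) <- list(rownames(values), colnames(S))
    coef
  }
}

#' Inverse spherical-harmonic transform
#'
#' Reconstructs the spatial field at the basis points from real harmonic
#' coefficients: the matrix-vector product of the evaluation matrix with the
#' coefficient vector.
#'
#' @param coefs Numeric vector of length `(L+1)^2`.
#' @param basis A `harmonic_basis`.
#' @return Numeric vector, one value per point.
#' @export
sht_inverse <- function(coefs, basis) {
  stopifnot(inherits(basis, "harmonic_basis"))
  if (length(coefs) != ncol(basis$matrix)) {
    stop("sht_inverse: coefficient length ", length(coefs),
         " does not match basis with ", ncol(basis$matrix), " columns")
  }
  drop(basis$matrix %*% coefs)
}

#' Low-frequency column window
#'
#' The first `J` columns of the deterministic basis ordering (lowest degrees
#' first) — the frequency set carrying the nonstationary random effects.
#'
#' @param J Number of columns, `1 <= J <= (L+1)^2`.
#' @param basis A `harmonic_basis`.
#' @return Integer vector of column indices.
#' @export
frequency_set <- function(J, basis) {
  stopifnot(inherits(basis, "harmonic_basis"))
  J <- as.integer(J)
  if (J < 1L || J > ncol(basis$matrix)) {
    stop("frequency_set requires 1 <= J <= ", ncol(basis$matrix))
  }
  seq_len(J)
}
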