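test_that("associated Legendre functions match known values and the reference implementation", {
  expect_equal(assoc_legendre(0, 0, 0.3), 1.0)
  expect_equal(assoc_legendre(1, 0, 0.5), 0.5)
  expect_equal(assoc_legendre(2, 0, 1.0), 1.0)   # (3x^2 - 1)/2 at x = 1
  expect_equal(assoc_legendre(1, 1, 0), -1)      # Condon-Shortley phase
  # oracle: pracma::legendre (MATLAB convention, Condon-Shortley included)
  xs <- seq(-0.95, 0.95, by = 0.19)
  for (l in 0:6) {
    ref <- matrix(pracma::legendre(l, xs), nrow = l + 1)
    for (m in 0:l) {
      expect_equal(assoc_legendre(l, m, xs), unname(ref[m + 1, ]),
                   tolerance = 1e-12, label = sprintf("P_%d^%d", l, m))
    }
  }
  expect_error(assoc_legendre(1, 2, 0.5), "0 <= m <= l")
  expect_error(assoc_legendre(2, 1, 1.5), "\\[-1, 1\\]")
})

test_that("complex spherical harmonics follow the unnormalized definition", {
  p <- sphere_points(c(0.7, pi / 2, 2.1), c(0.3, 0, 5.0))
  expect_equal(spherical_harmonic(0, 0, p), complex(real = rep(1, 3)))
  expect_equal(Re(spherical_harmonic(1, 0, p))[2], 0)
  # l=1, m=1 at (pi/2, 0): P_1^1(0) e^0 = -1
  eq <- sphere_points(pi / 2, 0)
  expect_equal(spherical_harmonic(1, 1, eq), complex(real = -1))
  # general point: P_l^m(cos s1) * exp(-i m s2)
  v <- spherical_harmonic(2, 1, p)
  expect_equal(v, assoc_legendre(2, 1, cos(p$colatitude)) *
                 exp(complex(imaginary = -p$longitude)))
  expect_error(spherical_harmonic(1, 2, p), "\\|m\\| <= l")
})

test_that("basis column count is (L+1)^2, matching the explicit degree sum", {
  pts <- fib_points(12)
  for (L in 0:10) {
    b <- harmonic_basis(pts, L)
    brute <- sum(vapply(0:L, function(l) 2 * l + 1, 0))
    expect_identical(ncol(b$matrix), (L + 1L) * (L + 1L))
    expect_identical(ncol(b$matrix), as.integer(brute))
  }
  # 68 scattered regions at L = 7 -> 64 spectral terms
  expect_identical(ncol(harmonic_basis(make_atlas(1), 7)$matrix), 64L)
  # single point, L = 0: the 1 x 1 matrix [1]
  b0 <- harmonic_basis(sphere_points(1.1, 0.4), 0)
  expect_equal(unname(b0$matrix), matrix(1, 1, 1))
  expect_error(harmonic_basis(sphere_points(numeric(), numeric()), 2),
               "at least one")
})

test_that("forward and inverse transforms are mutually inverse on general-position points", {
  b <- harmonic_basis(fib_points(64), 7)
  set.seed(42)
  coefs <- stats::rnorm(64)
  field <- sht_inverse(coefs, b)
  expect_lt(max(abs(sht_forward(field, b) - coefs)), 1e-8)
  # oracle: direct solve of the square system
  direct <- solve(b$matrix, field)
  expect_lt(max(abs(direct - coefs)), 1e-7)
  # fewer points than columns is also exact through the inverse map
  b2 <- harmonic_basis(fib_points(30), 4)
  co2 <- stats::rnorm(25)
  expect_lt(max(abs(sht_forward(sht_inverse(co2, b2), b2) - co2)), 1e-8)
})

test_that("constant fields load only on the degree-0 coefficient", {
  b <- harmonic_basis(fib_points(40), 5)
  co <- sht_forward(rep(3.25, 40), b)
  expect_equal(unname(co[1]), 3.25, tolerance = 1e-10)
  expect_lt(max(abs(co[-1])), 1e-8)
  # a single basis column projects to the unit coefficient
  co2 <- sht_forward(b$matrix[, 7], b)
  expect_equal(unname(co2[7]), 1, tolerance = 1e-10)
  expect_lt(max(abs(co2[-7])), 1e-8)
  # single (0,0) coefficient reproduces the constant field
  e1 <- numeric(36); e1[1] <- 2.5
  expect_equal(sht_inverse(e1, b), rep(2.5, 40))
  expect_equal(sht_inverse(numeric(36), b), rep(0, 40))
  expect_error(sht_inverse(numeric(10), b), "does not match")
  expect_error(sht_forward(c(rep(1, 39), NA), b), "non-finite")
})

test_that("real representation preserves the energy of conjugate-symmetric complex fields", {
  pts <- fib_points(50)
  L <- 4
  b <- harmonic_basis(pts, L)
  set.seed(7)
  # build a real field from complex coefficients with conjugate symmetry
  # on the same Schmidt/(2l+1) scaling as the basis columns
  field <- numeric(50)
  sq_complex <- 0
  coef_real <- numeric(ncol(b$matrix))
  j <- 0
  for (l in 0:L) {
    for (m in 0:l) {
      scl <- sqrt(exp(lgamma(l - m + 1) - lgamma(l + m + 1))) / sqrt(2 * l + 1)
      S <- spherical_harmonic(l, m, pts) * scl
      if (m == 0) {
        a <- stats::rnorm(1)
        field <- field + a * Re(S)
        sq_complex <- sq_complex + a^2
        coef_real[(j <- j + 1)] <- a
      } else {
        cc <- complex(real = stats::rnorm(1), imaginary = stats::rnorm(1))
        # c S + conj(c S): contributes 2 Re(c S); energy |c|^2 on +/-m
        field <- field + 2 * Re(cc * S)
        sq_complex <- sq_complex + 2 * Mod(cc)^2
        coef_real[(j <- j + 1)] <- sqrt(2) * Re(cc)
        coef_real[(j <- j + 1)] <- -sqrt(2) * Im(cc)
      }
    }
  }
  got <- sht_forward(field, b)
  expect_equal(unname(got), coef_real, tolerance = 1e-8)
  expect_equal(sum(got^2), sq_complex, tolerance = 1e-10)
})

test_that("the low-frequency window takes the lowest-degree columns", {
  b <- harmonic_basis(fib_points(20), 3)
  expect_identical(frequency_set(1, b), 1L)
  w4 <- frequency_set(4, b)
  expect_identical(b$index$l[w4], c(0L, 1L, 1L, 1L))
  w9 <- frequency_set(9, b)
  expect_true(all(b$index$l[w9] <= 2))
  expect_identical(length(w9), 9L)
  expect_error(frequency_set(0, b), "1 <= J")
  expect_error(frequency_set(17, b), "1 <= J")
})

test_that("spherical point validation wraps longitude and bounds colatitude", {
  p <- sphere_points(1, 7)
  expect_lt(p$longitude, 2 * pi)
  expect_error(sphere_points(-0.5, 0), "colatitude")
  expect_error(sphere_points(NaN, 0), "finite")
})
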