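test_that("harmonic basis reproduces the oscillator spectrum and is orthonormal", {
  b <- harmonic_basis(1, 3)
  expect_equal(b$eigvals, c(0.5, 1.5, 2.5))
  b1 <- harmonic_basis(2.5, 1)
  expect_equal(sum(b1$values[, 1]^2 * b1$weights), 1, tolerance = 1e-12)
  b8 <- harmonic_basis(0.8, 8, n_quad = 2L * 8L + 4L)
  expect_lt(max(abs(basis_gram(b8) - diag(8))), 1e-10)
  expect_error(harmonic_basis(1, 20, n_quad = 12), "grid too coarse")
})

test_that("relaxed basis matches closed-form spectra", {
  rb <- relaxed_basis(nm_poly(c(0, 0, 0.5)), 1, 5, n_grid = 201, bounds = c(-8, 8))
  expect_lt(max(abs(rb$eigvals - (0:4 + 0.5))), 1e-6)
  expect_lt(max(abs(basis_gram(rb) - diag(5))), 1e-8)
  D <- 10; a <- 0.5
  mb <- relaxed_basis(nm_morse(D, a), 1, 5, n_grid = 401, bounds = c(-6, 14))
  expect_lt(max(abs(mb$eigvals - morse_levels(D, a, 0:4))), 1e-5)
  expect_error(relaxed_basis(nm_poly(c(0, 0, 0.5)), 1, 50, n_grid = 32), "exceeds")
})

test_that("relaxed harmonic basis converges pointwise to the analytic functions", {
  omega <- 0.9
  rb <- relaxed_basis(nm_poly(c(0, 0, 0.5 * omega^2)), omega, 4, n_grid = 401)
  ana <- ho_eigenfunctions(omega, 4, rb$grid)
  for (k in 1:4) {
    s <- sign(sum(rb$values[, k] * ana[, k]))   # align sign convention
    expect_lt(max(abs(rb$values[, k] - s * ana[, k])), 1e-5)
  }
})

test_that("ground eigenvalue is variationally monotone under grid refinement", {
  v <- nm_poly(c(0, 0, 0.5, 0.05, 0.01))
  e_coarse <- relaxed_basis(v, 1, 1, n_grid = 41)$eigvals[1]
  e_mid <- relaxed_basis(v, 1, 1, n_grid = 81)$eigvals[1]
  e_fine <- relaxed_basis(v, 1, 1, n_grid = 161)$eigvals[1]
  expect_gte(e_coarse, e_mid - 1e-12)
  expect_gte(e_mid, e_fine - 1e-12)
})

test_that("eigenfunction signs are deterministic and bases serialize", {
  rb1 <- relaxed_basis(nm_morse(5, 0.4), 1, 4)
  rb2 <- relaxed_basis(nm_morse(5, 0.4), 1, 4)
  expect_identical(rb1$values, rb2$values)
  path <- withr::local_tempfile(fileext = ".rds")
  write_basis(rb1, path)
  back <- read_basis(path)
  expect_identical(back$values, rb1$values)
  expect_identical(back$eigvals, rb1$eigvals)
})
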