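# closed-form one-dimensional matrix elements in the harmonic eigenbasis,
# from the ladder-operator algebra (the independent oracle for quadrature)
ho_Q_matrix <- function(N) {
  Qm <- matrix(0, N, N)
  for (k in seq_len(N - 1)) {
    Qm[k, k + 1] <- sqrt(k / 2)
    Qm[k + 1, k] <- sqrt(k / 2)
  }
  Qm
}
# <k|Q^2|h> at unit frequency: diagonal (2k+1)/2, second off-diagonal
# sqrt((k+1)(k+2))/2 (the truncated product Q %*% Q misses the corner
# contribution through level N, so it is not a valid reference)
ho_Q2_matrix <- function(N, omega = 1) {
  Qm <- diag((2 * (0:(N - 1)) + 1) / 2, N)
  for (k in 0:(N - 3)) {
    v <- sqrt((k + 1) * (k + 2)) / 2
    Qm[k + 1, k + 3] <- Qm[k + 3, k + 1] <- v
  }
  Qm / omega
}

test_that("one-body integrals match ladder-operator closed forms", {
  for (N in c(4L, 16L)) {
    b <- harmonic_basis(1, N)
    H <- one_body_integrals(b, nm_poly(c(0, 0, 0.5)), include_kinetic = TRUE)
    expect_lt(max(abs(H - diag(0:(N - 1) + 0.5, N))), 1e-9)
    Q1 <- one_body_integrals(b, nm_poly(c(0, 1)), include_kinetic = FALSE)
    expect_lt(max(abs(Q1 - ho_Q_matrix(N))), 1e-9)
    Q2 <- one_body_integrals(b, nm_poly(c(0, 0, 1)), include_kinetic = FALSE)
    expect_lt(max(abs(Q2 - ho_Q2_matrix(N))), 1e-9)
  }
  b <- harmonic_basis(1, 5)
  expect_identical(one_body_integrals(b, NULL, include_kinetic = FALSE),
                   matrix(0, 5, 5))
})

test_that("two-body integrals factorize for separable surfaces", {
  bi <- harmonic_basis(1, 5)
  bj <- harmonic_basis(1.7, 4)
  Qi <- one_body_integrals(bi, nm_poly(c(0, 1)), include_kinetic = FALSE)
  Qj <- one_body_integrals(bj, nm_poly(c(0, 1)), include_kinetic = FALSE)
  A <- two_body_integrals(bi, bj, nm_sprod(nm_poly(c(0, 1)), nm_poly(c(0, 1))))
  ref <- aperm(outer(Qi, Qj), c(1, 3, 2, 4))  # [k_i, k_j, h_i, h_j]
  expect_lt(max(abs(A - ref)), 1e-9)
  # Qi^2 Qj^2 against the analytic <k|Q^2|h> blocks
  A2 <- two_body_integrals(bi, bj, nm_poly2(rbind(0, 0, c(0, 0, 1))))
  expect_lt(max(abs(A2 - aperm(outer(ho_Q2_matrix(5), ho_Q2_matrix(4, 1.7)),
                               c(1, 3, 2, 4)))), 1e-9)
  expect_identical(two_body_integrals(bi, bj, nm_poly2(matrix(0))),
                   array(0, c(5, 4, 5, 4)))
})

test_that("blocks are Hermitian and stable under quadrature refinement", {
  # deep well so all six states are strongly bound and grid-converged
  b <- relaxed_basis(nm_morse(20, 0.5), 1, 6, n_grid = 401L, bounds = c(-2.5, 10))
  H <- one_body_integrals(b, nm_poly(c(0, 0.2, 0, 0.05)), include_kinetic = TRUE,
                          check_convergence = TRUE, conv_tol = 1e-8)
  expect_lt(max(abs(H - t(H))), 1e-10)
  A <- two_body_integrals(b, b, nm_sprod(nm_poly(c(0, 0.1)), nm_poly(c(0, 1))),
                          check_convergence = TRUE, conv_tol = 1e-8)
  # exchange symmetry within each mode: (k,h) <-> (h,k)
  expect_lt(max(abs(A - aperm(A, c(3, 4, 1, 2)))), 1e-10)
})

test_that("integral tables cover every declared block", {
  fx <- fixture_random_system(2, seed = 11)
  tab <- compute_integral_tables(fx$model, fx$bases)
  expect_length(tab$diag, 2)
  expect_named(tab$offdiag, "1,2")
  for (a in 1:2) for (i in 1:2)
    expect_lt(max(abs(tab$diag[[a]]$one[[i]] - t(tab$diag[[a]]$one[[i]]))), 1e-10)
  # missing coupling table triggers an assembly error
  tab$offdiag <- list()
  expect_error(assemble_hamiltonian(fx$model, fx$bases, tables = tab), "missing")
})
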