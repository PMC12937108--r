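test_that("harmonic eigenbasis yields the diagonal number-operator terms", {
  fx <- fixture_ho(omega = 1, N = 4L)
  tm <- fx$sqh$terms
  expect_equal(nrow(tm), 4L)           # off-diagonal entries screened away
  expect_true(all(tm$k1 == tm$h1))
  expect_equal(sort(tm$coeff), 0:3 + 0.5, tolerance = 1e-9)
})

test_that("a two-level system with constant coupling has exactly four terms", {
  fx <- fixture_rabi(coupling = 0.02, energy = 0.1)
  tm <- fx$sqh$terms
  expect_equal(nrow(tm), 4L)
  expect_equal(sum(tm$a == tm$b), 2L)
  cross <- tm[tm$a != tm$b, ]
  expect_setequal(paste(cross$a, cross$b), c("1 2", "2 1"))
  expect_equal(cross$coeff, c(0.02, 0.02))
})

test_that("term lists close under Hermitian conjugation", {
  fx <- fixture_random_system(2, seed = 11)
  expect_true(check_hermitian_closure(fx$sqh))
  broken <- fx$sqh
  broken$terms$coeff[which(broken$terms$a != broken$terms$b)[1]] <- 99
  expect_error(check_hermitian_closure(broken), "not closed")
})

test_that("term count scales as the order-2 composite count", {
  # one state, 2 modes, dense (non-separable) surfaces with no screening:
  # F0 + sum_i N_i^2 one-body + N_1^2 N_2^2 two-body terms
  N <- c(3L, 4L)
  w <- cm_to_au(c(1100, 1300))
  # asymmetric Gaussians in the dimensionless coordinate: every matrix
  # element is nonzero (no parity selection rule), nothing screens away
  g <- function(omega) function(Q) 0.05 * exp(-0.5 * (sqrt(omega) * Q - 0.3)^2)
  mod <- vibronic_model(c(1100, 1300), list(nmode_function(2,
    F0 = 0.02,
    one = list("1" = nm_func(g(w[1])), "2" = nm_func(g(w[2]))),
    two = list("1,2" = nm_func2(function(a, b)
      1e-3 * exp(-0.5 * (sqrt(w[1]) * a - 0.2)^2 - 0.5 * (sqrt(w[2]) * b + 0.4)^2))))))
  bases <- list(harmonic_basis(mod$omega[1], N[1]), harmonic_basis(mod$omega[2], N[2]))
  sqh <- assemble_hamiltonian(mod, bases, screen = 0)
  expect_equal(nrow(sqh$terms), 1L + sum(N^2) + prod(N^2))
})

test_that("the dense matrix agrees with an independent quadrature assembly", {
  # Route A: term list -> build_dense.  Route B: direct tensor-grid
  # quadrature of the full surfaces via evaluate_nmode plus Kronecker
  # kinetic/identity factors -- no second-quantization machinery involved.
  fx <- fixture_random_system(2, seed = 11, N = 4L)
  mod <- fx$model; bases <- fx$bases
  N <- vapply(bases, `[[`, integer(1), "N")
  T1 <- bases[[1]]$kinetic; T2 <- bases[[2]]$kinetic
  I1 <- diag(N[1]); I2 <- diag(N[2])
  quad2 <- function(f) {
    g1 <- bases[[1]]$grid; g2 <- bases[[2]]$grid
    V <- matrix(0, length(g1), length(g2))
    for (i in seq_along(g1)) V[i, ] <- vapply(g2, function(q2)
      evaluate_nmode(f, c(g1[i], q2)) - f$F0, numeric(1))
    # expand F(Q1,Q2)-F0 in the product basis by full 2D quadrature
    P1 <- bases[[1]]$values; P2 <- bases[[2]]$values
    H <- matrix(0, prod(N), prod(N))
    for (k1 in seq_len(N[1])) for (h1 in seq_len(N[1])) {
      prof <- colSums(P1[, k1] * P1[, h1] * bases[[1]]$weights * V)  # over g1
      blk <- crossprod(P2, (prof * bases[[2]]$weights) * P2)
      rows <- (k1 - 1) * N[2] + seq_len(N[2])
      cols <- (h1 - 1) * N[2] + seq_len(N[2])
      H[rows, cols] <- H[rows, cols] + blk
    }
    H
  }
  Dv <- prod(N)
  Href <- matrix(0, 2 * Dv, 2 * Dv)
  Tfull <- kronecker(T1, I2) + kronecker(I1, T2)
  for (a in 1:2) {
    idx <- (a - 1) * Dv + seq_len(Dv)
    Href[idx, idx] <- Tfull + quad2(mod$diag[[a]]) + mod$diag[[a]]$F0 * diag(Dv)
  }
  cpl <- quad2(mod$offdiag[["1,2"]]) + mod$offdiag[["1,2"]]$F0 * diag(Dv)
  Href[seq_len(Dv), Dv + seq_len(Dv)] <- cpl
  Href[Dv + seq_len(Dv), seq_len(Dv)] <- cpl
  expect_lt(max(abs(fx$dense$H - Href)), 1e-10)
})

test_that("the term-list interchange format round-trips bit-exactly", {
  fx <- fixture_random_system(2, seed = 11)
  path <- withr::local_tempfile(fileext = ".txt")
  write_term_list(fx$sqh, path)
  back <- read_term_list(path)
  expect_identical(back$terms$coeff, fx$sqh$terms$coeff)
  expect_identical(back$terms$i1, fx$sqh$terms$i1)
  expect_identical(back$N, fx$sqh$N)
  expect_identical(back$n_el, fx$sqh$n_el)
})
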