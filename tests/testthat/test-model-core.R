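test_that("n-mode evaluation is exactly additive over stored terms", {
  f <- nmode_function(2, F0 = 0.5,
                      one = list("1" = nm_func(function(Q) Q^2),
                                 "2" = nm_poly(c(0, 2))),
                      two = list("1,2" = nm_func2(function(a, b) a * b)))
  expect_identical(evaluate_nmode(nmode_function(3, F0 = 0.5), c(0, 1, 2)), 0.5)
  expect_equal(evaluate_nmode(f, c(1, 3)), 0.5 + 1 + 6 + 3)
  # brute-force sum over the stored terms, term by term
  Q <- c(1.3, -0.7)
  brute <- f$F0 + nm_eval1(f$one[["1"]], Q[1]) + nm_eval1(f$one[["2"]], Q[2]) +
    nm_eval2(f$two[["1,2"]], Q[1], Q[2])[1, 1]
  expect_equal(evaluate_nmode(f, Q), brute, tolerance = 1e-15)
  expect_error(evaluate_nmode(f, c(1)), "dimension mismatch")
})

test_that("n-mode function constructors validate their keys", {
  expect_error(nmode_function(2, one = list("3" = nm_poly(1))), "1..M")
  expect_error(nmode_function(3, two = list("2,2" = nm_poly2(diag(2)))), "i < j")
  expect_error(nm_morse(-1, 0.5), "D > 0")
})

test_that("displaced harmonic oscillator generator has the analytic geometry", {
  m <- make_displaced_ho_model(1, d = 1, dE = 0)
  v <- m$diag[[1]]
  expect_equal(evaluate_nmode(v, 1), 0)
  expect_equal(evaluate_nmode(v, 0), 0.5)
  expect_equal(m$meta$huang_rhys, 0.5)
  # minimum location and curvature by finite differences
  h <- 1e-4
  grad <- (evaluate_nmode(v, 1 + h) - evaluate_nmode(v, 1 - h)) / (2 * h)
  curv <- (evaluate_nmode(v, 1 + h) - 2 * evaluate_nmode(v, 1) +
             evaluate_nmode(v, 1 - h)) / h^2
  expect_lt(abs(grad), 1e-6)
  expect_lt(abs(curv - 1), 1e-6)
  m0 <- make_displaced_ho_model(1, d = 0, dE = 0.3)
  expect_equal(evaluate_nmode(m0$diag[[1]], 0), 0.3)
  expect_error(make_displaced_ho_model(-1, 0), "positive")
})

test_that("two-state generator covers the closed-form limits", {
  # Morse diagonal evaluates to zero at its minimum
  morse <- nmode_function(1, one = list("1" = nm_morse(0.1, 0.7)))
  m <- make_coupled_two_state_model(1500, morse, morse,
                                    nmode_function(1, F0 = 1e-3))
  expect_equal(evaluate_nmode(m$diag[[2]], 0), 0)
  # zero coupling: the dense Hamiltonian is block diagonal
  m0 <- make_coupled_two_state_model(
    au_to_cm(1),
    nmode_function(1, one = list("1" = nm_poly(c(0, 0, 0.5)))),
    nmode_function(1, F0 = 0.1, one = list("1" = nm_poly(c(0, 0, 0.5)))),
    nmode_function(1, F0 = 0))
  sys <- build_dense(assemble_hamiltonian(m0, list(harmonic_basis(1, 4))))
  offblock <- sys$H[1:4, 5:8]
  expect_lt(max(abs(offblock)), 1e-12)
  # constant coupling c between degenerate states: Rabi period pi/c
  fx <- fixture_rabi(coupling = 0.02)
  sys2 <- build_dense(fx$sqh)
  pr <- dense_propagate(sys2, c(1, 0) + 0i, pi / 0.02)
  expect_equal(pr$populations[1, 1], 1, tolerance = 1e-10)
})

test_that("random model generator is deterministic and Hermitian downstream", {
  m1 <- random_vibronic_model(2, seed = 4)
  m2 <- random_vibronic_model(2, seed = 4)
  expect_identical(m1$freqs_cm, m2$freqs_cm)
  expect_identical(m1$diag[[2]]$one[["1"]]$coef, m2$diag[[2]]$one[["1"]]$coef)
  fx <- fixture_random_system(2, seed = 11)
  expect_lt(max(abs(fx$dense$H - t(fx$dense$H))), 1e-12 * max(abs(fx$dense$H)))
})

test_that("model files round-trip through YAML", {
  mod <- random_vibronic_model(2, seed = 8)
  mod$diag[[1]]$one[["2"]] <- nm_morse(0.2, 0.4, Q0 = 1.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model(mod, path)
  back <- read_model(path)
  expect_equal(back$freqs_cm, mod$freqs_cm)
  Q <- c(0.3, -1.2)
  for (a in 1:2)
    expect_equal(evaluate_nmode(back$diag[[a]], Q), evaluate_nmode(mod$diag[[a]], Q),
                 tolerance = 1e-12)
  expect_equal(evaluate_nmode(back$offdiag[["1,2"]], Q),
               evaluate_nmode(mod$offdiag[["1,2"]], Q), tolerance = 1e-12)
  expect_error(read_model(withr::local_tempfile()), "not found")
})
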