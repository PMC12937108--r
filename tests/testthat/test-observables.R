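test_that("the Condon state is the all-zeros product state on the target surface", {
  fx <- fixture_random_system(2, seed = 11)
  psi <- condon_initial_state(fx$lattice, 2, mu = dipole_model(0.7))
  expect_equal(mps_norm(psi), 1)
  expect_equal(populations(psi), c(0, 1))
  expect_equal(attr(psi, "mu0"), 0.7)
  ref <- product_state(fx$lattice, 2)
  expect_equal(Mod(mps_overlap(ref, psi)), 1, tolerance = 1e-12)
  vac <- product_state(fx$lattice, 0)
  expect_equal(abs(mps_overlap(vac, psi)), 0)
  expect_error(condon_initial_state(fx$lattice, 3), "out of range")
})

test_that("stationary states keep |C(t)| = 1 and populations in [0,1] sum to 1", {
  fx <- fixture_ho(omega = 1, N = 6L)
  psi0 <- product_state(fx$lattice, 1, occ = 1L)
  out <- tdvp_propagate(psi0, fx$mpo, dt = 0.2, n_steps = 50, units = "au",
                        cutoff = 0, record_energy = FALSE)
  ac <- autocorrelation(out$record)
  expect_lt(max(abs(Mod(ac$C) - 1)), 1e-9)
  fr <- fixture_random_system(2, seed = 11)
  psi <- random_mps(fr$lattice, 3, seed = 2)
  p <- populations(psi)
  expect_true(all(p >= -1e-12 & p <= 1 + 1e-12))
  expect_equal(sum(p), 1, tolerance = 1e-8)
})

test_that("the displaced oscillator reproduces the analytic autocorrelation", {
  w <- 1; S <- 0.5
  mod <- make_displaced_ho_model(w, d = sqrt(2 * S / w), dE = 0)
  sqh <- assemble_hamiltonian(mod, list(harmonic_basis(w, 18)))
  mpo <- compile_mpo(sqh)
  psi0 <- condon_initial_state(mps_lattice(1, 18L), 1)
  out <- tdvp_propagate(psi0, mpo, dt = 2 * pi / 20, n_steps = 100, units = "au",
                        m_max = Inf, cutoff = 0, expand = "full",
                        record_energy = FALSE)
  ac <- autocorrelation(out$record)
  tt <- fs_to_au(ac$times_fs)
  exact <- exp(-S * (1 - exp(-1i * w * tt)) - 1i * (w / 2) * tt)
  expect_lt(max(Mod(ac$C - exact)), 1e-5)
})

test_that("decoupled states propagate block-diagonally", {
  mod <- make_coupled_two_state_model(
    au_to_cm(1),
    nmode_function(1, one = list("1" = nm_poly(c(0, 0, 0.5)))),
    nmode_function(1, F0 = 0.2, one = list("1" = nm_poly(c(0.18, -0.6, 0.5)))),
    nmode_function(1, F0 = 0))
  b <- list(harmonic_basis(1, 8))
  sqh <- assemble_hamiltonian(mod, b)
  mpo <- compile_mpo(sqh)
  lat <- mps_lattice(2, 8L)
  psi0 <- condon_initial_state(lat, 2)
  out <- tdvp_propagate(psi0, mpo, dt = 0.3, n_steps = 60, units = "au",
                        m_max = Inf, cutoff = 0, expand = "full",
                        record_energy = FALSE)
  # populations constant, and C(t) equals the excited-block autocorrelation
  expect_lt(max(abs(out$record$pop.2 - 1)), 1e-10)
  sys <- build_dense(sqh)
  blk <- sys$H[9:16, 9:16]
  ee <- eigen(blk, symmetric = TRUE)
  a <- crossprod(ee$vectors, c(1, rep(0, 7)))
  tt <- fs_to_au(out$record$time_fs)
  Cblk <- vapply(tt, function(t) sum(a^2 * exp(-1i * ee$values * t)), complex(1))
  ac <- autocorrelation(out$record)
  expect_lt(max(Mod(ac$C - Cblk)), 1e-8)
})

test_that("Rabi populations follow the two-level closed form through TDVP", {
  fx <- fixture_rabi(coupling = 0.02)
  psi0 <- condon_initial_state(fx$lattice, 1)
  out <- tdvp_propagate(psi0, fx$mpo, dt = 0.5, n_steps = 120, m_max = Inf,
                        cutoff = 0, record_energy = FALSE)
  tt <- fs_to_au(out$record$time_fs)
  expect_lt(max(abs(out$record$pop.1 - cos(fx$coupling * tt)^2)), 1e-6)
})

test_that("the spectrum of a pure phase is a single peak at its frequency", {
  E <- 0.35
  tt <- seq(0, 400, by = 0.5)
  rec <- list(times_fs = au_to_fs(tt), C = exp(-1i * E * tt))
  spec <- absorption_spectrum(rec, unit = "au")
  pk <- find_peaks(spec, floor = 0.5)
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$omega - E), 2 * pi / max(tt))
  # zero series maps to a zero spectrum
  rec0 <- list(times_fs = au_to_fs(tt), C = 0i * tt)
  expect_equal(max(absorption_spectrum(rec0, unit = "au")$magnitude), 0)
  # the 0-0 shift moves the axis exactly
  spec_s <- absorption_spectrum(rec, shift = 0.1, unit = "au")
  expect_equal(spec_s$omega - spec$omega, rep(0.1, nrow(spec)), tolerance = 1e-12)
  expect_error(absorption_spectrum(list(times_fs = c(0, 1, 3), C = c(1, 1, 1) + 0i)),
               "not uniform")
})

test_that("peaks appear only at oracle eigenvalue differences", {
  fx <- fixture_random_system(2, seed = 11)
  psi0 <- condon_initial_state(fx$lattice, 2)
  tt <- fs_to_au(0.5) * seq(0, 600)
  ex <- dense_propagate(fx$dense, mps_dense_vector(psi0), tt)
  rec <- list(times_fs = au_to_fs(tt), C = ex$autocorr)
  spec <- absorption_spectrum(rec, unit = "au")
  pk <- find_peaks(spec, floor = 0.05)
  # every detected peak lies within a grid spacing of some eigenvalue
  dw <- 2 * pi / max(tt)
  for (om in pk$omega)
    expect_lt(min(abs(ex$eigenvalues - om)), dw)
})

test_that("the integrated spectrum is stable when the window doubles", {
  fx <- fixture_rabi(coupling = 0.01, energy = 0.15)
  psi0 <- condon_initial_state(fx$lattice, 1)
  mk <- function(n) {
    out <- tdvp_propagate(psi0, fx$mpo, dt = 1, n_steps = n, m_max = Inf,
                          cutoff = 0, record_energy = FALSE)
    # Gaussian damping makes C(t) decay inside both windows
    absorption_spectrum(out$record, unit = "au", broadening = 1500)
  }
  s1 <- mk(1500); s2 <- mk(3000)
  p1 <- sum(s1$magnitude^2) * (s1$omega[2] - s1$omega[1])
  p2 <- sum(s2$magnitude^2 * (s2$omega <= max(s1$omega))) * (s2$omega[2] - s2$omega[1])
  expect_lt(abs(p1 - p2) / p1, 0.05)
})
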