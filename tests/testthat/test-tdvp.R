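test_that("a zero Hamiltonian leaves the state untouched", {
  fx <- fixture_rabi()
  zero <- fx$sqh
  zero$terms <- zero$terms[0, ]
  mpo0 <- compile_mpo(sq_hamiltonian(zero$terms, 2L, integer()))
  psi0 <- product_state(fx$lattice, 1)
  out <- tdvp_propagate(psi0, mpo0, dt = 1, n_steps = 5, cutoff = 0)
  C <- complex(real = out$record$re_C, imaginary = out$record$im_C)
  expect_lt(max(Mod(C - 1)), 1e-12)
})

test_that("an eigenstate accumulates the stationary phase exp(-iEt)", {
  fx <- fixture_ho(omega = 1, N = 6L)
  psi0 <- product_state(fx$lattice, 1, occ = 2L)
  out <- tdvp_propagate(psi0, fx$mpo, dt = 0.1, n_steps = 100, units = "au",
                        cutoff = 0)
  C <- complex(real = out$record$re_C, imaginary = out$record$im_C)
  tt <- fs_to_au(out$record$time_fs)
  expect_lt(max(Mod(C - exp(-1i * 2.5 * tt))), 1e-8)
})

test_that("full-bond-dimension TDVP reproduces the dense propagator", {
  fx <- fixture_random_system(2, seed = 11)
  psi0 <- condon_initial_state(fx$lattice, 2)
  out <- tdvp_propagate(psi0, fx$mpo, dt = 0.5, n_steps = 100, m_max = Inf,
                        cutoff = 0, expand = "full")
  tt <- fs_to_au(out$record$time_fs)
  ex <- dense_propagate(fx$dense, mps_dense_vector(psi0), tt)
  C <- complex(real = out$record$re_C, imaginary = out$record$im_C)
  expect_lt(max(Mod(C - ex$autocorr)), 1e-6)
  pops <- as.matrix(out$record[, c("pop.1", "pop.2")])
  expect_lt(max(abs(pops - ex$populations)), 1e-6)
})

test_that("norm, energy and total electronic population are conserved", {
  fx <- fixture_random_system(2, seed = 11)
  psi0 <- condon_initial_state(fx$lattice, 2)
  out <- tdvp_propagate(psi0, fx$mpo, dt = 0.5, n_steps = 100, m_max = Inf,
                        cutoff = 1e-12, expand = "full")
  expect_lt(max(abs(out$record$norm - 1)), 1e-8)
  drift <- abs(out$record$energy - out$record$energy[1])
  expect_lt(max(drift) / abs(out$record$energy[1]), 1e-6)
  # truncated run: populations still sum to one at every step
  outT <- tdvp_propagate(psi0, fx$mpo, dt = 0.5, n_steps = 60, m_max = 3L)
  expect_lt(max(abs(out$record$pop.1 + out$record$pop.2 - 1)), 1e-8)
  expect_lt(max(abs(outT$record$pop.1 + outT$record$pop.2 - 1)), 1e-8)
  # truncated bond never exceeds the pre-truncation rank
  expect_true(all(outT$record$bond_post <= outT$record$bond_pre))
  expect_true(all(outT$record$bond_post <= 3L))
})

test_that("autocorrelation error decreases monotonically with bond dimension", {
  fx <- fixture_random_system(2, seed = 11)
  psi0 <- condon_initial_state(fx$lattice, 2)
  tt <- fs_to_au(0.5) * seq(0, 80)
  ex <- dense_propagate(fx$dense, mps_dense_vector(psi0), tt)
  errs <- vapply(c(2, 4, Inf), function(m) {
    out <- tdvp_propagate(psi0, fx$mpo, dt = 0.5, n_steps = 80, m_max = m,
                          expand = if (is.finite(m)) "none" else "full",
                          cutoff = if (is.finite(m)) 1e-12 else 0,
                          record_energy = FALSE)
    C <- complex(real = out$record$re_C, imaginary = out$record$im_C)
    max(Mod(C - ex$autocorr))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-12))
})

test_that("the one-step probe error vanishes with the step and for diagonal models", {
  fx <- fixture_random_system(3, seed = 11, N = 5L)
  psi <- product_state(fx$lattice, 2)
  e_big <- step_error_probe(psi, fx$mpo, fx$sqh, 2, units = "fs", cutoff = 0)
  e_small <- step_error_probe(psi, fx$mpo, fx$sqh, 0.25, units = "fs", cutoff = 0)
  expect_lt(e_small, e_big)
  expect_lt(e_small, 1e-3)
  # non-interacting diagonal model: the sweep splitting is exact
  ho <- fixture_ho(omega = 1, N = 6L)
  pho <- product_state(ho$lattice, 1, occ = 1L)
  expect_lt(step_error_probe(pho, ho$mpo, ho$sqh, 5, units = "au", cutoff = 0),
            1e-9)
})

test_that("imaginary-time propagation relaxes toward the ground state", {
  fx <- fixture_random_system(2, seed = 11)
  psi0 <- random_mps(fx$lattice, 4, seed = 2)
  out <- tdvp_propagate(psi0, fx$mpo, dt = 40, n_steps = 60, units = "au",
                        m_max = 20L, imag_time = TRUE)
  e_final <- out$record$energy[nrow(out$record)]
  expect_lt(e_final - dense_ground_energy(fx$dense), 1e-6)
})
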