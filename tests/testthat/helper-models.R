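# Shared fixtures, built once per test run.  Everything is generated in
# code from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

# seeded random two-state model with ground-state relaxed bases and all
# derived objects (term list, MPO, dense oracle)
fixture_random_system <- function(M = 2L, seed = 11L, N = 6L, n_grid = 201L) {
  key <- sprintf("rs_%d_%d_%d", M, seed, N)
  if (!is.null(.fixture_env[[key]])) return(.fixture_env[[key]])
  mod <- random_vibronic_model(M, seed = seed)
  bases <- lapply(seq_len(M), function(i)
    relaxed_basis(mod$diag[[1]]$one[[as.character(i)]], mod$omega[i], N,
                  n_grid = n_grid))
  sqh <- assemble_hamiltonian(mod, bases)
  fx <- list(model = mod, bases = bases, sqh = sqh,
             mpo = compile_mpo(sqh),
             lattice = mps_lattice(mod$n_el, sqh$N),
             dense = build_dense(sqh))
  .fixture_env[[key]] <- fx
  fx
}

# degenerate two-level system with constant coupling (Rabi fixture)
fixture_rabi <- function(coupling = 0.02, energy = 0.1) {
  mod <- make_coupled_two_state_model(
    numeric(0),
    nmode_function(0, F0 = energy), nmode_function(0, F0 = energy),
    nmode_function(0, F0 = coupling))
  sqh <- assemble_hamiltonian(mod, list())
  list(model = mod, sqh = sqh, mpo = compile_mpo(sqh),
       lattice = mps_lattice(2), coupling = coupling)
}

# one-mode harmonic oscillator quantized in its own eigenbasis
fixture_ho <- function(omega = 1, N = 6L) {
  mod <- vibronic_model(au_to_cm(omega),
                        list(nmode_function(1, one = list("1" = nm_poly(c(0, 0, 0.5 * omega^2))))))
  sqh <- assemble_hamiltonian(mod, list(harmonic_basis(omega, N)))
  list(model = mod, sqh = sqh, mpo = compile_mpo(sqh),
       lattice = mps_lattice(1, N), omega = omega)
}
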