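test_that("product states have unit norm, indicator populations and orthogonality", {
  fx <- fixture_random_system(2, seed = 11)
  p <- product_state(fx$lattice, 2)
  expect_equal(mps_norm(p), 1)
  expect_equal(populations(p), c(0, 1))
  p2 <- product_state(fx$lattice, 2, occ = c(1L, 0L))
  expect_equal(abs(mps_overlap(p, p2)), 0)
  vac <- product_state(fx$lattice, 0)
  expect_equal(abs(mps_overlap(vac, p)), 0)     # different charge sectors
  expect_error(product_state(fx$lattice, 5), "out of range")
  expect_error(product_state(fx$lattice, 1, occ = c(9L, 0L)), "out of range")
})

test_that("compiled MPOs reconstruct the oracle matrix entrywise", {
  fx <- fixture_ho(omega = 1, N = 5L)
  expect_lt(max(Mod(mpo_dense_matrix(fx$mpo) - build_dense(fx$sqh)$H)), 1e-10)
  fr <- fixture_random_system(2, seed = 11)
  expect_lt(max(Mod(mpo_dense_matrix(fr$mpo) - fr$dense$H)), 1e-10)
  expect_equal(mpo_bond_dims(identity_mpo(fr$lattice)), rep(1L, 3))
})

test_that("composite vibrational operators are exact matrix units", {
  # E_kh E_h'k' = delta(h, h') E_kk', and all local dimensions are N_i
  # (no auxiliary vacuum level anywhere)
  N <- 5L
  for (k in 1:3) for (h in 1:3) for (h2 in 1:3) for (k2 in 1:3) {
    prod_op <- vibronmps:::.op_bos(paste("E", k, h, sep = ","), N) %*%
      vibronmps:::.op_bos(paste("E", h2, k2, sep = ","), N)
    ref <- if (h == h2) vibronmps:::.op_bos(paste("E", k, k2, sep = ","), N)
           else matrix(0i, N, N)
    expect_identical(prod_op, ref)
  }
  fx <- fixture_random_system(2, seed = 11)
  for (s in seq_len(fx$lattice$L)) {
    dw <- dim(fx$mpo$W[[s]])
    expect_identical(dw[2], fx$lattice$dims[s])   # physical dims exactly N_i
    expect_identical(dw[3], fx$lattice$dims[s])
  }
})

test_that("expectation and overlap agree with dense contraction", {
  fx <- fixture_random_system(2, seed = 11)
  psi <- random_mps(fx$lattice, 4, seed = 3)
  phi <- random_mps(fx$lattice, 3, seed = 9)
  v <- mps_dense_vector(psi); u <- mps_dense_vector(phi)
  expect_lt(Mod(mps_expectation(psi, fx$mpo) - sum(Conj(v) * (fx$dense$H %*% v))), 1e-10)
  expect_lt(abs(Im(mps_expectation(psi, fx$mpo))), 1e-10)
  expect_lt(Mod(mps_overlap(phi, psi) - sum(Conj(u) * v)), 1e-12)
  expect_equal(Mod(mps_overlap(psi, psi)), 1, tolerance = 1e-12)
  bad <- random_mps(mps_lattice(2, c(5, 5)), 2, seed = 1)
  expect_error(mps_overlap(bad, psi), "lattice mismatch")
})

test_that("canonicalization and truncation preserve or bound the state faithfully", {
  fx <- fixture_random_system(2, seed = 11)
  psi <- random_mps(fx$lattice, 6, seed = 7)
  v <- mps_dense_vector(psi)
  for (ctr in c(1L, 3L, fx$lattice$L)) {
    psic <- canonicalize(psi, ctr)
    expect_lt(max(Mod(mps_dense_vector(psic) - v)), 1e-12)
  }
  # lossless truncation: m_max at least the current bonds
  tr0 <- truncate_mps(psi, max(mps_bond_dims(psi)), cutoff = 0)
  expect_equal(tr0$discarded, 0)
  expect_equal(Mod(mps_overlap(tr0$psi, psi)), 1, tolerance = 1e-12)
  # single-bond truncation: fidelity = 1 - discarded, against the dense SVD
  psic <- canonicalize(psi, 3L)
  th <- vibronmps:::bond_tensor(psic, 3L)
  sp <- vibronmps:::split_bond(psic, 3L, th, m_max = 3L, cutoff = 0)
  expect_equal(Mod(mps_overlap(sp$psi, psi))^2 / mps_norm(sp$psi)^2,
               1 - sp$discarded, tolerance = 1e-10)
  # dense SVD oracle for the same cut: best rank-3 squared error equals
  # the discarded weight; rebuild the chain-ordered vector, cut after site 3
  dims <- fx$lattice$dims
  vc <- complex(prod(dims))
  vc[vibronmps:::.oracle_chain_indices(fx$lattice)] <- v
  Mcut <- matrix(vc, prod(dims[1:3]))
  sv <- svd(Mcut)$d
  expect_equal(sp$discarded, sum(sv[-(1:3)]^2), tolerance = 1e-10)
  # product state singular spectra are all {1}
  p <- product_state(fx$lattice, 1)
  trp <- truncate_mps(p, 1L, cutoff = 0)
  expect_equal(trp$discarded, 0)
})

test_that("U(1) bookkeeping survives every operation", {
  fx <- fixture_random_system(2, seed = 11)
  psi <- random_mps(fx$lattice, 5, seed = 13)
  expect_lt(mps_charge_audit(psi), 1e-14)
  expect_lt(mps_charge_audit(canonicalize(psi, 4L)), 1e-13)
  expect_lt(mps_charge_audit(truncate_mps(psi, 2L)$psi), 1e-13)
  expect_lt(mps_charge_audit(mps_expand_bonds(product_state(fx$lattice, 2))), 1e-13)
  expect_equal(mps_total_charge(psi), 1L)
})

test_that("bond expansion pads ranks without touching the state", {
  fx <- fixture_random_system(2, seed = 11)
  p <- product_state(fx$lattice, 2)
  pe <- mps_expand_bonds(p)
  expect_identical(mps_bond_dims(pe), c(2L, 2L, 6L))
  expect_lt(max(Mod(mps_dense_vector(pe) - mps_dense_vector(p))), 1e-13)
})
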