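---
title: "Vibronic wavepacket dynamics with n-mode Hamiltonians and matrix product states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vibronic wavepacket dynamics with n-mode Hamiltonians and matrix product states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vibronmps)
```

## The model

`vibronmps` treats molecular photodynamics in a diabatic picture. For
`N_el` electronic states and `M` mass-weighted vibrational modes
`Q = (Q_1, ..., Q_M)` the Hamiltonian is the block operator whose diagonal
blocks are vibrational Hamiltonians `H_α = T + v_α(Q)` and whose
off-diagonal blocks are real nonadiabatic coupling surfaces `V_αβ(Q)`.
The kinetic operator is taken as `T = -1/2 Σ_i ∂²/∂Q_i²` in atomic units
with `ħ = 1`; this is the standard form for mass-weighted normal
coordinates and is consistent with the per-mode harmonic reference
frequencies `ω_i` that the model carries (converters for cm⁻¹, eV and fs
are exported). Rotational and Watson-type kinetic couplings are outside
the scope.

Every surface — diagonal potential or coupling — is stored as an n-mode
(many-body) expansion

    F(Q) = F0 + Σ_i F1[i](Q_i) + Σ_{i<j} F2[ij](Q_i, Q_j) + ...

with declarative term types (`nm_poly`, `nm_morse`, `nm_grid`, `nm_poly2`,
`nm_sprod`, opaque functions as an escape hatch). The expansion carries an
explicit constant term even though the many-body decomposition itself does
not need one: vertical electronic energies and constant interstate
couplings live there, which keeps a single container type for every block.
Couplings are stored once per unordered state pair and applied
Hermitianly; complex couplings are rejected because all integrals assume a
real-valued basis. Three-body terms are accepted structurally (the file
format and containers reserve them) but are not evaluated into integrals:
the applications targeted here include up to two-body terms, and the hook
keeps the interface stable if that changes.

## Modal bases and integrals

Each mode gets a one-dimensional orthonormal basis `{φ_k}` tabulated on a
quadrature grid:

* `harmonic_basis(omega, N)` — analytic oscillator eigenfunctions on a
  Gauss–Hermite grid scaled by `sqrt(omega)`; the default quadrature order
  `2N + 16` integrates products of basis functions times low-order
  polynomials exactly, and every basis checks the normalization of its
  highest function to 1e-8 at construction.
* `relaxed_basis(v1, omega_ref, N)` — the lowest `N` eigenfunctions of
  `T + v1` on a uniform grid via the Colbert–Miller discrete variable
  representation. This is the default pipeline choice with `v1` the
  ground-state one-body potential, so the initial (Condon) wavepacket is a
  single basis state. Displaced or Morse-adapted bases can be requested
  explicitly by passing any other `v1`.

Grid bounds default to ±7 ground-state classical turning points of the
reference frequency (`±7/sqrt(omega_ref)`), 301 uniform points; both are
configurable, and `refine_basis()` doubles the resolution for convergence
checks. Eigenfunction signs are fixed deterministically (positive at the
leftmost antinode) so that integrals are bit-reproducible across runs.

One-body blocks are quadrature sums `⟨φ_k|v|φ_h⟩` plus an exact kinetic
matrix: closed-form ladder-operator elements for harmonic bases, and
`E_k δ_kh − ⟨φ_k|v₁|φ_h⟩` for relaxed bases (exact in the DVR sense).
Two-body blocks use the tensor product of the per-mode rules; sparse or
Smolyak grids are deliberately not implemented at desk scale. Entries
below a screening threshold (default 1e-12 hartree) are dropped before
operator assembly.

## Second quantization and the lattice

Quantizing every block in the modal bases produces a term list

    Σ  c · a†_α a_β · Π_i (b†_{k_i} b_{h_i})

over a one-dimensional lattice with the `N_el` electronic sites (physical
dimension 2, occupations 0/1) at the head, followed by one site per mode
in ascending frequency order. Two conventions matter:

* **Composite local operators.** The product `b†_k b_h` is stored as one
  `N_i × N_i` matrix unit per site. Registering creation and annihilation
  separately would require an auxiliary vacuum level and `(N_i+1)`-
  dimensional operators; the composite form makes the vacuum redundant.
  Factors on distinct modes commute, so a two-body string is exactly the
  pair of per-mode composites.
* **U(1) symmetry.** Total electronic occupation is conserved (one quantum
  in the excited manifold). Every MPS bond index carries the cumulative
  electronic occupation to its left; tensors are zero outside
  charge-consistent blocks, and all QR/SVD factorizations are performed
  sector by sector, so the block structure is exact by construction
  (`mps_charge_audit()` verifies it). Electronic sites are hard-core
  bosonic: with total charge one and single-transfer terms `a†_α a_β`,
  exchange statistics are unobservable, so no Jordan–Wigner strings are
  needed.

The MPO is compiled from the term list by a prefix automaton (channels
keyed by the operator string already emitted; coefficients attached at a
term's last non-identity site) followed by a two-direction SVD compression
sweep with relative cutoff 1e-13, which merges shared factors and brings
bond dimensions close to the numerical rank. Dense reconstructions of
compiled MPOs agree with the directly assembled matrix to well below
1e-10 on all tested instances.

One practical subtlety: the renormalized two-site problems contain U(1)
sectors that are unphysical for the propagated state (for example the
empty electronic configuration, an exact eigenvector at the zero of
energy). Round-off can seed amplitudes there, and an iterative eigensolver
will happily converge to such a spurious solution. All local Krylov solves
therefore mask their iterates to the physical charge block.

## Ground states and time evolution

`dmrg_ground()` is a standard two-site DMRG: each microiteration solves
the effective eigenproblem in the renormalized basis with a restarted
Lanczos (full reorthogonalization, residual tolerance 1e-9, the current
two-site tensor as the starting vector) and splits the optimized tensor by
a sector-wise truncated SVD. A sweep visits every bond left-to-right and
back; convergence is declared when the sweep energy changes by less than
the tolerance. The effective operator's Hermiticity is probed once per run
and an asymmetry above 1e-8 is a hard error.

`tdvp_propagate()` is the tangent-space two-site integrator. One time step
is one full sweep: on the forward pass every two-site block is evolved by
`exp(-i H_eff dt/2)` and every interior single site back-evolved by
`exp(+i K_eff dt/2)`; the backward pass mirrors it. The palindromic
ordering makes the step formally second order. Local exponentials use
Lanczos with tolerance 1e-10 and an adaptive Krylov dimension capped at 30
(non-convergence is an error, not a warning). After every SVD the state is
truncated to the bond-dimension cap `m_max`, discarding relative squared
singular values below `cutoff` (default 1e-12); the record keeps the
pre/post-truncation bond dimensions and the cumulative discarded weight,
which is the intrinsic error measure of the method. An `imag_time` flag
replaces `-i` by `-1` with per-step renormalization for relaxation runs.
Defaults mirror typical application settings: `dt = 0.5` fs with one sweep
per step (800 steps for 400 fs).

Two further design choices deserve a note:

* **Half-step scheduling.** With one sweep advancing one step, the split
  of the step across the two passes is a genuine convention; this package
  fixes the symmetric forward-half/backward-half scheme described above.
* **Full-rank bond expansion.** `expand = "full"` pads the initial state's
  bonds with zero-weight orthonormal states up to the exact sector
  capacities (`mps_expand_bonds()`). With complete local bases every
  effective Hamiltonian equals the full Hamiltonian and the sweep
  telescopes to the exact propagator, so "full bond dimension" runs are
  limited only by the Krylov tolerance. This is how oracle-equivalence
  checks are run.

* **Observed step-size order.** `step_error_probe()` measures the one-step
  error against the dense propagator. Empirically the measured order
  depends on the regime: from a rank-deficient (product/Condon) start the
  leading error is the `dt²` term from bond growth saturating within a
  single sweep (observed order ≈ 2); once rank effects are absent the
  symmetric splitting error is below `dt³` (observed orders 4–5 on
  nearest-neighbour chains); and at full rank the step is exact. The
  often-quoted third-order local error is an upper bound for the splitting
  component alone and is not the leading term of this implementation in
  any tested regime — the probe reports what it measures.

## Observables and spectra

The Condon excitation places the vibrational ground wavepacket on the
target surface; in the ground-state eigenbasis that is the all-zeros
product state, with the constant transition dipole recorded as an overall
intensity scale. The autocorrelation `C(t) = ⟨ψ(0)|ψ(t)⟩` is accumulated
every step, populations are expectation values of the electronic number
operators (their sum is identically one in the charge-1 sector — a check
on the U(1) bookkeeping, not an assumption), and the absorption spectrum
is the half-line transform `I(ω) = Σ_n w_n e^{iω t_n} C(t_n) dt` with
trapezoid end weights, evaluated on the grid `ω_j = 2πj/T`. The magnitude
`|I(ω)|` is reported and the 0–0 shift is recorded in the metadata. No
zero padding and no broadening are applied by default; both exist as
flags. `find_peaks()` locates local maxima above a relative floor (default
1% of the global maximum) with three-point parabolic refinement.

A windowing detail worth knowing: with an undamped `C(t)` the finite
window produces Dirichlet-kernel sidelobes. When the propagation time is
an integer number of periods of the line spacing, the discrete trapezoid
transform evaluated at the resonances is exactly crosstalk-free — the
Franck–Condon verification below exploits this, which is why its intensity
check passes at the 1e-9 level rather than the few-percent level a generic
window would give.

## What the synthetic models emulate

`random_vibronic_model(M, seed)` generates the two-state, few-mode
anharmonic benchmark family used throughout the tests: frequencies drawn
from 800–1800 cm⁻¹, per-state displaced wells with dimensionless
displacements up to ±0.8 and small cubic/quartic distortions (expressed in
the dimensionless coordinate `u = sqrt(ω) Q`, quartic coefficients kept
positive so the surfaces are bound), bilinear two-body couplings within
each state, and interstate couplings of a few millihartree with constant
plus linear terms. These magnitudes are typical of mid-size organic
chromophores with moderate nonadiabatic coupling; what the generator does
*not* emulate are conical-intersection topologies (degeneracy seams),
double-well surfaces, very-low-frequency large-amplitude modes, and
high-order coupling terms. Passing tests therefore demonstrate the
correctness of the machinery on bound, moderately anharmonic, weakly-to-
moderately coupled models — they do not by themselves certify accuracy
for strong conical-intersection dynamics.

`make_displaced_ho_model()` provides the analytically solvable
displaced-oscillator limit (Huang–Rhys factor `S = ωd²/2`, Poisson
Franck–Condon intensities `e^{-S}Sⁿ/n!`), and the degenerate two-level
fixture has the `cos²(ct)` Rabi closed form. The dense oracle
(`build_dense()`, `dense_propagate()`) builds the full direct-product
Hamiltonian from the same term list (hard cap 20 000 basis states,
overridable) and propagates by eigendecomposition; it is the verification
reference for every tensor-network result.

## Problem sizes and numerical choices

The verification suite runs at desk scale on one CPU: oracle-equivalence
dynamics on a 2-state/2-mode model with 6 basis functions per mode (dense
dimension 72, 200 steps of 0.5 fs); MPO reconstruction on ten seeded
models with dense dimensions between 50 and 432; convergence morphology on
a 2-state/3-mode model through bond dimensions {2, 4, 8, full} over 100 fs
and local basis sizes {4, 8, 12} over 150 fs with bond dimension 10.
Degenerate singular values are broken deterministically (descending order,
stable sector ordering, keep-first); truncation keeps at most `m_max`
values per bond and drops relative squared weights below 1e-12; MPO
compression uses a 1e-13 relative cutoff; integral screening is 1e-12
hartree. Quadrature bounds and resolutions are exposed in the
configuration because finer grids and larger bounds are the first knobs to
turn when tighter integrals are needed.

## Limitations

No time-dependent Hamiltonians (laser fields), no finite-temperature
propagation, no tree tensor networks or mode-reordering optimization, no
VSCF-style coupled-mode modal optimization, no derivative (kinetic)
couplings in the off-diagonal blocks — couplings are potential-only, and
three-body integrals are a format hook, not an implementation. The dense
oracle is exact but capped; beyond its reach, convergence must be judged
from the discarded weight and bond-dimension/basis-size scans, as in the
morphology checks.
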