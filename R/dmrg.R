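# Two-site ground-state DMRG: sweeps optimize each pair of neighboring
# sites by solving the effective eigenvalue problem in the renormalized
# basis (Lanczos), then split the optimized bond tensor by a sector-wise
# truncated SVD.

# environments: LE[[s]] is the left environment for site s (contraction of
# sites < s), RE[[s]] the right environment (contraction of sites > s).
.init_envs <- function(psi, mpo) {
  L <- psi$lattice$L
  LE <- vector("list", L + 1L)
  RE <- vector("list", L + 2L)
  LE[[1]] <- array(1 + 0i, c(1, 1, 1))
  RE[[L + 1L]] <- array(1 + 0i, c(1, 1, 1))
  for (s in seq(L, 2L))
    RE[[s]] <- contract_env_right(RE[[s + 1L]], psi$A[[s]], mpo$W[[s]], psi$A[[s]])
  list(LE = LE, RE = RE)
}

.heff2_fun <- function(LE, W1, W2, RE, dims, mask = NULL) {
  force(LE); force(W1); force(W2); force(RE); force(dims); force(mask)
  function(x) {
    if (!is.null(mask)) x <- x * mask
    dim(x) <- dims
    y <- as.vector(apply_heff2(LE, W1, W2, RE, x))
    if (!is.null(mask)) y * mask else y
  }
}

.heff1_fun <- function(LE, W, RE, dims, mask = NULL) {
  force(LE); force(W); force(RE); force(dims); force(mask)
  function(x) {
    if (!is.null(mask)) x <- x * mask
    dim(x) <- dims
    y <- as.vector(apply_heff1(LE, W, RE, x))
    if (!is.null(mask)) y * mask else y
  }
}

# charge-consistency masks: 1 where the leg charges balance, 0 elsewhere.
# Round-off can seed amplitudes in foreign U(1) sectors of the renormalized
# two-site problem (which contain spurious low eigenvalues, e.g. the empty
# electronic configuration at energy zero); masking the Krylov iterates
# keeps every local solve inside the physical sector.
.theta_mask2 <- function(psi, s) {
  lat <- psi$lattice
  ql <- psi$bq[[s]]; c1 <- lat$charges[[s]]; c2 <- lat$charges[[s + 1L]]
  qr <- psi$bq[[s + 2L]]
  lhs <- outer(outer(ql, c1, `+`), c2, `+`)
  as.numeric(outer(lhs, qr, `==`))
}

.site_mask1 <- function(psi, s) {
  ql <- psi$bq[[s]]; cs <- psi$lattice$charges[[s]]; qr <- psi$bq[[s + 1L]]
  as.numeric(outer(outer(ql, cs, `+`), qr, `==`))
}

# Hermiticity probe of an effective operator (random vectors, fixed draw)
.check_hermitian_heff <- function(afun, n, tol = 1e-8) {
  u <- complex(real = sin(seq_len(n)), imaginary = cos(1.3 * seq_len(n)))
  v <- complex(real = cos(2.1 * seq_len(n)), imaginary = sin(0.7 * seq_len(n)))
  u <- u / sqrt(sum(Mod(u)^2)); v <- v / sqrt(sum(Mod(v)^2))
  a <- sum(Conj(u) * afun(v)); b <- sum(Conj(afun(u)) * v)
  scale <- max(1, Mod(a), Mod(b))
  if (Mod(a - b) > tol * scale)
    stop(sprintf("effective Hamiltonian asymmetry %.3g exceeds %.3g", Mod(a - b), tol))
  invisible(TRUE)
}

#' Two-site ground-state DMRG
#'
#' Variational minimization of `<psi|H|psi>` over MPSs of maximum bond
#' dimension `m_max` by sweeping two-site microiterations (Lanczos on the
#' effective Hamiltonian, sector-wise truncated SVD).  A sweep optimizes
#' every lattice site from the head of the chain to its end and back;
#' convergence is declared when the inter-sweep energy change falls below
#' `tol`.
#'
#' @param psi0 initial `vibronic_mps` (e.g. [random_mps()] or a product
#'   state in the right charge sector).
#' @param mpo Hermitian `vibronic_mpo`.
#' @param m_max maximum bond dimension.
#' @param n_sweeps maximum number of sweeps.
#' @param tol inter-sweep energy convergence threshold (hartree).
#' @param cutoff relative squared singular-value truncation threshold.
#' @param lanczos_tol residual tolerance of the local eigensolver.
#' @return list with `psi` (optimized state, normalized), `energy`, and
#'   `report` (a data frame with per-sweep energy, maximum bond dimension
#'   and maximum discarded weight, plus attribute `micro` with per-site
#'   microiteration energies).
#' @export
dmrg_ground <- function(psi0, mpo, m_max = 50L, n_sweeps = 20L, tol = 1e-10,
                        cutoff = 1e-14, lanczos_tol = 1e-9) {
  L <- psi0$lattice$L
  if (L < 2) stop("DMRG needs at least two sites")
  psi <- canonicalize(psi0, 1L)
  psi <- mps_scale(psi, 1 / mps_norm(psi))
  env <- .init_envs(psi, mpo)
  LE <- env$LE; RE <- env$RE
  energy <- NA_real_
  rows <- list(); micro_all <- list()
  checked <- FALSE
  for (sw in seq_len(n_sweeps)) {
    micro <- numeric(); maxdisc <- 0
    sweep_sites <- c(seq_len(L - 1L), seq(L - 1L, 1L))
    dir <- rep(c("r", "l"), c(L - 1L, L - 1L))
    for (k in seq_along(sweep_sites)) {
      s <- sweep_sites[k]
      th <- bond_tensor(psi, s)
      dims <- dim(th)
      afun <- .heff2_fun(LE[[s]], mpo$W[[s]], mpo$W[[s + 1L]], RE[[s + 2L]], dims,
                         mask = .theta_mask2(psi, s))
      if (!checked) { .check_hermitian_heff(afun, prod(dims)); checked <- TRUE }
      sol <- lanczos_ground(afun, as.vector(th), tol = lanczos_tol)
      energy <- sol$value
      micro <- c(micro, energy)
      th <- array(sol$vector, dims)
      sp <- split_bond(psi, s, th, m_max, cutoff,
                       keep = if (dir[k] == "r") "right" else "left")
      psi <- sp$psi
      maxdisc <- max(maxdisc, sp$discarded)
      if (dir[k] == "r") {
        LE[[s + 1L]] <- contract_env_left(LE[[s]], psi$A[[s]], mpo$W[[s]], psi$A[[s]])
      } else {
        RE[[s + 1L]] <- contract_env_right(RE[[s + 2L]], psi$A[[s + 1L]],
                                           mpo$W[[s + 1L]], psi$A[[s + 1L]])
      }
    }
    rows[[sw]] <- data.frame(sweep = sw, energy = energy,
                             max_bond = max(mps_bond_dims(psi)),
                             max_discarded = maxdisc)
    micro_all[[sw]] <- micro
    if (sw > 1 && abs(rows[[sw]]$energy - rows[[sw - 1L]]$energy) < tol) break
  }
  report <- do.call(rbind, rows)
  attr(report, "micro") <- micro_all
  psi <- mps_scale(psi, 1 / mps_norm(psi))
  list(psi = psi, energy = energy, report = report)
}
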