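# Tangent-space two-site TD-DMRG.  One sweep (forward over every bond with
# half the time step, then backward with the other half) advances the state
# by one time step: each two-site block is evolved by exp(-i H_eff dt/2)
# (Lanczos exponential), split by a sector-wise truncated SVD back onto the
# bond-dimension manifold, and each interior single site is back-evolved by
# exp(+i K_eff dt/2).  The symmetric ordering makes the integrator second
# order in the time step with third-order local error.

#' Propagate an MPS with the two-site TDVP integrator
#'
#' @param psi0 normalized initial `vibronic_mps`.
#' @param mpo Hermitian `vibronic_mpo` (time independent).
#' @param dt time step, in fs by default.
#' @param n_steps number of steps (one sweep each).
#' @param m_max maximum bond dimension during truncation.
#' @param cutoff relative squared singular-value truncation threshold.
#' @param units `"fs"` or `"au"` for `dt`.
#' @param imag_time propagate in imaginary time (`exp(-H t)`, with
#'   per-step renormalization) instead of real time?
#' @param expand `"none"` keeps the initial bond dimensions; `"full"`
#'   pads the initial state's bonds to `min(m_max, sector capacity)` with
#'   zero-weight orthonormal states before propagating, so the effective
#'   Hamiltonians act in complete local bases from the first step.
#' @param krylov_tol,krylov_max tolerance and dimension cap of the local
#'   Lanczos exponentials.
#' @param record_energy evaluate `<H>` at every step (one extra contraction
#'   sweep)?
#' @param observer optional `function(psi, step)` called after every step.
#' @return list with `psi` (final state) and `record`, a data frame of
#'   class `propagation_record` with per-step time (fs), complex
#'   autocorrelation `C(t) = <psi(0)|psi(t)>`, diabatic populations
#'   `pop.1..pop.n_el` (normalized), `norm`, `energy`, maximum bond
#'   dimension before/after truncation, and cumulative discarded weight.
#' @export
tdvp_propagate <- function(psi0, mpo, dt, n_steps, m_max = Inf,
                           cutoff = 1e-12, units = c("fs", "au"),
                           imag_time = FALSE, expand = c("none", "full"),
                           krylov_tol = 1e-10, krylov_max = 30L,
                           record_energy = TRUE, observer = NULL) {
  units <- match.arg(units)
  expand <- match.arg(expand)
  dt_au <- if (units == "fs") fs_to_au(dt) else dt
  lat <- psi0$lattice
  L <- lat$L
  if (L < 2) stop("TDVP needs at least two sites")
  psi <- canonicalize(psi0, 1L)
  if (expand == "full") psi <- canonicalize(mps_expand_bonds(psi, m_max), 1L)
  ref <- psi0                       # autocorrelation reference
  tau <- if (imag_time) -dt_au / 2 else -1i * dt_au / 2
  nops <- stats::setNames(lapply(seq_len(lat$n_el), function(g) .op_elec("n")),
                          as.character(seq_len(lat$n_el)))
  env <- .init_envs(psi, mpo)
  LE <- env$LE; RE <- env$RE
  disc_cum <- 0
  snap <- function(step, bond_pre, bond_post) {
    nrm <- mps_norm(psi)
    pops <- Re(mps_site_expectations(psi, nops)) / nrm^2
    en <- if (record_energy) Re(mps_expectation(psi, mpo)) / nrm^2 else NA_real_
    c(time_fs = au_to_fs(step * dt_au), re_C = NA, im_C = NA,
      stats::setNames(pops, paste0("pop.", seq_len(lat$n_el))),
      norm = nrm, energy = en, bond_pre = bond_pre, bond_post = bond_post,
      discarded = disc_cum)
  }
  rows <- vector("list", n_steps + 1L)
  r0 <- snap(0, max(mps_bond_dims(psi)), max(mps_bond_dims(psi)))
  C0 <- mps_overlap(ref, psi)
  r0["re_C"] <- Re(C0); r0["im_C"] <- Im(C0)
  rows[[1]] <- r0
  checked <- FALSE
  for (step in seq_len(n_steps)) {
    bond_pre <- 0L
    # ---- forward half sweep
    for (s in seq_len(L - 1L)) {
      th <- bond_tensor(psi, s)
      dims <- dim(th)
      afun <- .heff2_fun(LE[[s]], mpo$W[[s]], mpo$W[[s + 1L]], RE[[s + 2L]], dims,
                         mask = .theta_mask2(psi, s))
      if (!checked) { .check_hermitian_heff(afun, prod(dims)); checked <- TRUE }
      thv <- krylov_expm(afun, as.vector(th), tau, tol = krylov_tol, maxk = krylov_max)
      bond_pre <- max(bond_pre, .theta_rank(psi, s, dims))
      sp <- split_bond(psi, s, array(thv, dims), m_max, cutoff, keep = "right")
      psi <- sp$psi
      disc_cum <- disc_cum + sp$discarded
      LE[[s + 1L]] <- contract_env_left(LE[[s]], psi$A[[s]], mpo$W[[s]], psi$A[[s]])
      if (s < L - 1L) {
        A <- psi$A[[s + 1L]]; da <- dim(A)
        k1 <- .heff1_fun(LE[[s + 1L]], mpo$W[[s + 1L]], RE[[s + 2L]], da,
                         mask = .site_mask1(psi, s + 1L))
        Av <- krylov_expm(k1, as.vector(A), -tau, tol = krylov_tol, maxk = krylov_max)
        psi$A[[s + 1L]] <- array(Av, da)
      }
    }
    # ---- backward half sweep
    for (s in seq(L - 1L, 1L)) {
      th <- bond_tensor(psi, s)
      dims <- dim(th)
      afun <- .heff2_fun(LE[[s]], mpo$W[[s]], mpo$W[[s + 1L]], RE[[s + 2L]], dims,
                         mask = .theta_mask2(psi, s))
      thv <- krylov_expm(afun, as.vector(th), tau, tol = krylov_tol, maxk = krylov_max)
      bond_pre <- max(bond_pre, .theta_rank(psi, s, dims))
      sp <- split_bond(psi, s, array(thv, dims), m_max, cutoff, keep = "left")
      psi <- sp$psi
      disc_cum <- disc_cum + sp$discarded
      RE[[s + 1L]] <- contract_env_right(RE[[s + 2L]], psi$A[[s + 1L]],
                                         mpo$W[[s + 1L]], psi$A[[s + 1L]])
      if (s > 1L) {
        A <- psi$A[[s]]; da <- dim(A)
        k1 <- .heff1_fun(LE[[s]], mpo$W[[s]], RE[[s + 1L]], da,
                         mask = .site_mask1(psi, s))
        Av <- krylov_expm(k1, as.vector(A), -tau, tol = krylov_tol, maxk = krylov_max)
        psi$A[[s]] <- array(Av, da)
      }
    }
    if (imag_time) psi <- mps_scale(psi, 1 / mps_norm(psi))
    r <- snap(step, bond_pre, max(mps_bond_dims(psi)))
    Ct <- mps_overlap(ref, psi)
    r["re_C"] <- Re(Ct); r["im_C"] <- Im(Ct)
    rows[[step + 1L]] <- r
    if (!is.null(observer)) observer(psi, step)
  }
  record <- as.data.frame(do.call(rbind, rows))
  class(record) <- c("propagation_record", class(record))
  attr(record, "settings") <- list(dt = dt, units = units, n_steps = n_steps,
                                   m_max = m_max, cutoff = cutoff,
                                   imag_time = imag_time, expand = expand,
                                   krylov_tol = krylov_tol, krylov_max = krylov_max)
  list(psi = psi, record = record)
}

# maximal untruncated rank the evolved two-site tensor could carry
.theta_rank <- function(psi, s, dims) {
  min(dims[1] * dims[2], dims[3] * dims[4])
}

#' @export
print.propagation_record <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<propagation_record> %d steps to t = %.4g fs; final |C| = %.4g, max bond %d\n",
              n - 1L, x$time_fs[n], sqrt(x$re_C[n]^2 + x$im_C[n]^2),
              max(x$bond_post)))
  invisible(x)
}

#' One-step local-error probe of the TDVP integrator
#'
#' Performs a single TDVP step of size `dt` from `psi` and measures the
#' 2-norm distance of the resulting dense state vector from the exact
#' propagation `exp(-i H dt) psi` computed with the dense oracle.  Halving
#' `dt` should reduce the result about eightfold (third-order local error)
#' whenever the tangent-space projection is the leading error.
#'
#' @param psi a normalized `vibronic_mps`.
#' @param mpo the compiled `vibronic_mpo`.
#' @param sqh the matching `sq_hamiltonian` (for the dense oracle).
#' @param dt step size.
#' @param units `"fs"` or `"au"`.
#' @param m_max bond-dimension cap applied during the step.
#' @param dim_cap largest dense dimension accepted for the oracle.
#' @param ... further arguments to [tdvp_propagate()].
#' @return the local error (2-norm).
#' @export
step_error_probe <- function(psi, mpo, sqh, dt, units = c("fs", "au"),
                             m_max = Inf, dim_cap = 20000L, ...) {
  units <- match.arg(units)
  dt_au <- if (units == "fs") fs_to_au(dt) else dt
  sys <- build_dense(sqh, dim_cap = dim_cap)
  v0 <- mps_dense_vector(psi)
  ex <- dense_propagate(sys, v0, dt_au)
  out <- tdvp_propagate(psi, mpo, dt, 1L, m_max = m_max, units = units,
                        record_energy = FALSE, ...)
  v1 <- mps_dense_vector(out$psi)
  sqrt(sum(Mod(v1 - ex$states[, 1])^2))
}
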