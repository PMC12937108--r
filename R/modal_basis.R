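# Per-mode single-particle (modal) bases on quadrature grids.
# Two constructions: analytic harmonic-oscillator eigenfunctions on a scaled
# Gauss-Hermite grid, and "relaxed" eigenfunctions of T + v1 on a uniform
# grid via the Colbert-Miller discrete variable representation.  Every basis
# carries its quadrature rule, tabulated values and the exact kinetic-energy
# matrix in its own span, so downstream integrals need only pointwise
# products and weights.

#' Modal basis object
#'
#' A set of `N` orthonormal one-dimensional basis functions for a single
#' vibrational mode, tabulated on a quadrature grid.  Fields: `N`, `grid`
#' (nodes), `weights` (quadrature weights for plain `dQ` integration),
#' `values` (`length(grid) x N` matrix), `eigvals` (1D energies when the
#' basis is an eigenbasis, else `NULL`), `kinetic` (`N x N` matrix of
#' `-1/2 d^2/dQ^2` in the basis), `omega_ref`, and the constructor `spec`
#' for refinement checks.
#'
#' @name modal_basis
NULL

.new_basis <- function(N, grid, weights, values, eigvals, kinetic, omega_ref, spec) {
  N <- as.integer(N)
  structure(list(N = N, grid = grid, weights = weights, values = values,
                 eigvals = eigvals, kinetic = kinetic, omega_ref = omega_ref,
                 spec = spec),
            class = "modal_basis")
}

#' @export
print.modal_basis <- function(x, ...) {
  cat(sprintf("<modal_basis> N = %d (%s), %d grid points on [%.3g, %.3g]\n",
              x$N, x$spec$type, length(x$grid), min(x$grid), max(x$grid)))
  invisible(x)
}

#' Gram matrix of a modal basis on its quadrature
#' @param basis a `modal_basis`.
#' @return the `N x N` overlap matrix; identity for a valid basis.
#' @export
basis_gram <- function(basis) {
  crossprod(basis$values, basis$values * basis$weights)
}

#' Analytic harmonic-oscillator eigenfunctions
#'
#' Tabulates the first `N` eigenfunctions of `-1/2 d^2/dQ^2 + 1/2 omega^2 Q^2`
#' on a Gauss-Hermite grid scaled by `sqrt(omega)`.  Eigenvalues are
#' `omega*(k + 1/2)` and the kinetic matrix uses the ladder-operator closed
#' form.  The quadrature order must resolve the highest function; the
#' normalization of every function on the grid is checked to 1e-8.
#'
#' @param omega frequency (a.u.), positive.
#' @param N number of basis functions.
#' @param n_quad number of Gauss-Hermite nodes; default `2*N + 16`.
#' @return a `modal_basis`.
#' @export
harmonic_basis <- function(omega, N, n_quad = NULL) {
  if (!is.finite(omega) || omega <= 0) stop("omega must be positive")
  stopifnot(N >= 1)
  if (is.null(n_quad)) n_quad <- 2L * N + 16L
  gh <- pracma::gaussHermite(n_quad)
  Q <- gh$x / sqrt(omega)
  wts <- gh$w * exp(gh$x^2) / sqrt(omega)   # weights for plain dQ integration
  values <- ho_eigenfunctions(omega, N, Q)
  nrm <- colSums(values^2 * wts)
  if (any(abs(nrm - 1) > 1e-8))
    stop("grid too coarse: highest harmonic function not normalized to 1e-8")
  # <k|T|h> = omega/4 * [(2k+1) d_kh - sqrt((k+1)(k+2)) d_{h,k+2} - sqrt(k(k-1)) d_{h,k-2}]
  k <- 0:(N - 1)
  Tm <- diag(omega / 4 * (2 * k + 1), N)
  if (N > 2) {
    for (kk in 0:(N - 3)) {
      val <- -omega / 4 * sqrt((kk + 1) * (kk + 2))
      Tm[kk + 1, kk + 3] <- val
      Tm[kk + 3, kk + 1] <- val
    }
  }
  .new_basis(N, Q, wts, values, omega * (k + 0.5), Tm, omega,
             list(type = "harmonic", omega = omega, N = N, n_quad = n_quad))
}

#' Tabulate analytic harmonic-oscillator eigenfunctions
#'
#' @param omega frequency (a.u.).
#' @param N number of functions.
#' @param Q coordinate vector.
#' @return `length(Q) x N` matrix with `phi_k(Q)` in column `k+1`.
#' @export
ho_eigenfunctions <- function(omega, N, Q) {
  u <- sqrt(omega) * Q
  vals <- matrix(0, length(Q), N)
  vals[, 1] <- pi^(-0.25) * exp(-u^2 / 2)
  if (N >= 2) vals[, 2] <- sqrt(2) * u * vals[, 1]
  if (N >= 3) for (k in 2:(N - 1))
    vals[, k + 1] <- sqrt(2 / k) * u * vals[, k] - sqrt((k - 1) / k) * vals[, k - 1]
  vals * omega^0.25
}

#' Relaxed (potential-adapted) modal basis
#'
#' Lowest `N` eigenfunctions of the one-dimensional Hamiltonian
#' `-1/2 d^2/dQ^2 + v1(Q)` on a uniform grid, using the Colbert-Miller
#' discrete variable representation of the kinetic operator.  This is the
#' construction used for ground-state vibrational eigenbases.  The sign of
#' each eigenfunction is fixed so that its value at the leftmost antinode
#' (first grid point where the amplitude exceeds a tenth of its maximum) is
#' positive, making downstream integrals reproducible.
#'
#' @param v1 potential: an `nm_term`, a function, or an `nmode_function`
#'   with `M = 1` (evaluated along its single mode).
#' @param omega_ref reference frequency (a.u.) used for default grid bounds
#'   `+/- 7/sqrt(omega_ref)` (seven ground-state classical turning points).
#' @param N number of eigenfunctions requested.
#' @param n_grid number of uniform grid points (default 301).
#' @param bounds optional `c(Qmin, Qmax)` overriding the default.
#' @return a `modal_basis` with ascending `eigvals`.
#' @export
relaxed_basis <- function(v1, omega_ref, N, n_grid = 301L, bounds = NULL) {
  stopifnot(N >= 1, n_grid >= 16)
  if (N > n_grid) stop("N exceeds the number of grid states")
  if (inherits(v1, "nmode_function")) {
    stopifnot(v1$M == 1)
    f0 <- v1$F0; t1 <- v1$one[["1"]]
    v1 <- if (is.null(t1)) nm_poly(f0) else t1
    if (f0 != 0 && !identical(v1$type, "poly"))
      v1 <- nm_func(local({ tt <- v1; cc <- f0; function(Q) nm_eval1(tt, Q) + cc }))
    else if (f0 != 0) v1$coef[1] <- v1$coef[1] + f0
  }
  v1 <- .as_term1(v1)
  if (is.null(bounds)) {
    stopifnot(is.finite(omega_ref), omega_ref > 0)
    bounds <- c(-7, 7) / sqrt(omega_ref)
  }
  Q <- seq(bounds[1], bounds[2], length.out = n_grid)
  dQ <- Q[2] - Q[1]
  Vg <- nm_eval1(v1, Q)
  if (any(!is.finite(Vg))) stop("potential not evaluable on the grid")
  # Colbert-Miller uniform-grid DVR kinetic matrix
  jj <- outer(seq_len(n_grid), seq_len(n_grid), `-`)
  Tm <- (-1)^jj / (2 * dQ^2) * ifelse(jj == 0, pi^2 / 3, 2 / jj^2)
  ee <- eigen(Tm + diag(Vg, n_grid), symmetric = TRUE)
  ord <- seq(n_grid, n_grid - N + 1L)
  vals <- ee$vectors[, ord, drop = FALSE] / sqrt(dQ)
  evs <- ee$values[ord]
  for (k in seq_len(N)) {
    v <- vals[, k]
    first <- which(abs(v) > 0.1 * max(abs(v)))[1]
    if (v[first] < 0) vals[, k] <- -v
  }
  .new_basis(N, Q, rep(dQ, n_grid), vals, evs, diag(evs, N) - crossprod(vals, vals * (dQ * Vg)),
             omega_ref,
             list(type = "relaxed", v1 = v1, omega_ref = omega_ref, N = N,
                  n_grid = n_grid, bounds = bounds))
}

#' Rebuild a basis with a refined quadrature/grid
#'
#' Doubles the number of quadrature nodes (harmonic) or grid points
#' (relaxed); used for quadrature-convergence checks.
#'
#' @param basis a `modal_basis`.
#' @return a refined `modal_basis`.
#' @export
refine_basis <- function(basis) {
  s <- basis$spec
  switch(s$type,
    harmonic = harmonic_basis(s$omega, s$N, 2L * s$n_quad),
    relaxed = relaxed_basis(s$v1, s$omega_ref, s$N, 2L * s$n_grid - 1L, s$bounds),
    stop("cannot refine basis of type ", s$type)
  )
}

#' Closed-form Morse oscillator levels
#'
#' Bound-state energies of `D*(1-exp(-a*Q))^2` with unit mass and `hbar = 1`:
#' `E_n = w0*(n+1/2) - (w0*(n+1/2))^2/(4D)` with `w0 = a*sqrt(2D)`, for
#' `n + 1/2 < sqrt(2D)/a`.
#'
#' @param D well depth (hartree).
#' @param a range parameter.
#' @param n vector of quantum numbers.
#' @return energies (hartree).
#' @export
morse_levels <- function(D, a, n) {
  w0 <- a * sqrt(2 * D)
  lam <- sqrt(2 * D) / a
  if (any(n + 0.5 >= lam)) stop("requested Morse level is not bound")
  w0 * (n + 0.5) - (w0 * (n + 0.5))^2 / (4 * D)
}

#' Serialize / restore a modal basis
#'
#' Writes the basis (grid, weights, values, eigenvalues, kinetic matrix) to a
#' versioned binary container for caching, and reads it back.
#'
#' @param basis a `modal_basis`.
#' @param path file path.
#' @return `read_basis` returns the restored `modal_basis`.
#' @export
write_basis <- function(basis, path) {
  saveRDS(list(container = "vibronmps_basis", version = 1L, basis = unclass(basis)), path)
  invisible(path)
}

#' @rdname write_basis
#' @export
read_basis <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container, "vibronmps_basis")) stop("not a basis container")
  structure(obj$basis, class = "modal_basis")
}
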