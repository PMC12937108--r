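# Numerical one- and two-body matrix elements of n-mode expansion terms in
# the modal bases.  One-body blocks are quadrature sums over the basis grid
# (plus the exact kinetic matrix carried by the basis when requested);
# two-body blocks use the tensor product of the per-mode quadrature rules.

#' One-body integrals
#'
#' Computes the `N x N` block `H[k,h] = <phi_k| T + v1 |phi_h>` by quadrature
#' on the basis grid.  For coupling surfaces set `include_kinetic = FALSE`
#' to obtain the potential-only block `<phi_k| V1 |phi_h>`.
#'
#' @param basis a `modal_basis`.
#' @param v1 one-body term (`nm_term`, function, or `NULL` for none).
#' @param include_kinetic add the kinetic-energy matrix of the basis?
#' @param check_convergence if `TRUE`, recompute on a refined grid and raise
#'   an error when any entry changes by more than `conv_tol`.
#' @param conv_tol tolerance for the convergence check.
#' @return dense symmetric `N x N` matrix.
#' @export
one_body_integrals <- function(basis, v1 = NULL, include_kinetic = TRUE,
                               check_convergence = FALSE, conv_tol = 1e-8) {
  stopifnot(inherits(basis, "modal_basis"))
  H <- matrix(0, basis$N, basis$N)
  if (!is.null(v1)) {
    v1 <- .as_term1(v1)
    Vg <- nm_eval1(v1, basis$grid)
    if (any(!is.finite(Vg))) stop("one-body term not evaluable on the basis grid")
    H <- crossprod(basis$values, basis$values * (basis$weights * Vg))
    H <- (H + t(H)) / 2
  }
  if (include_kinetic) H <- H + basis$kinetic
  if (check_convergence) {
    H2 <- one_body_integrals(refine_basis(basis), v1, include_kinetic)
    if (max(abs(H2 - H)) > conv_tol)
      stop(sprintf("quadrature not converged: refinement changes entries by %.3g",
                   max(abs(H2 - H))))
  }
  H
}

#' Two-body integrals
#'
#' Computes the four-index block
#' `H[k_i, k_j, h_i, h_j] = <phi_ki phi_kj| v2 |phi_hi phi_hj>` by
#' tensor-product quadrature on the two basis grids.
#'
#' @param basis_i,basis_j `modal_basis` objects for the two modes.
#' @param v2 two-body term (`nm_term2` or function of two coordinates).
#' @param check_convergence,conv_tol as in [one_body_integrals()].
#' @return array of dimension `c(N_i, N_j, N_i, N_j)`.
#' @export
two_body_integrals <- function(basis_i, basis_j, v2,
                               check_convergence = FALSE, conv_tol = 1e-8) {
  stopifnot(inherits(basis_i, "modal_basis"), inherits(basis_j, "modal_basis"))
  v2 <- .as_term2(v2)
  Vg <- nm_eval2(v2, basis_i$grid, basis_j$grid)
  if (any(!is.finite(Vg))) stop("two-body term not evaluable on the grid")
  Ni <- basis_i$N; Nj <- basis_j$N
  ni <- length(basis_i$grid); nj <- length(basis_j$grid)
  # P[g, (k,h)] = phi_k(g) phi_h(g), k fastest
  Pi <- basis_i$values[, rep(seq_len(Ni), Ni)] * basis_i$values[, rep(seq_len(Ni), each = Ni)]
  Pj <- basis_j$values[, rep(seq_len(Nj), Nj)] * basis_j$values[, rep(seq_len(Nj), each = Nj)]
  A <- crossprod(Pi * basis_i$weights, Vg %*% (Pj * basis_j$weights))
  # A[(k_i,h_i), (k_j,h_j)] -> array [k_i, k_j, h_i, h_j]
  dim(A) <- c(Ni, Ni, Nj, Nj)
  A <- aperm(A, c(1, 3, 2, 4))
  if (check_convergence) {
    A2 <- two_body_integrals(refine_basis(basis_i), refine_basis(basis_j), v2)
    if (max(abs(A2 - A)) > conv_tol)
      stop(sprintf("two-body quadrature not converged: refinement changes entries by %.3g",
                   max(abs(A2 - A))))
  }
  A
}

#' Integral tables for a vibronic model
#'
#' Evaluates every one- and two-body block needed to second-quantize a
#' vibronic model in the supplied per-mode bases: for each electronic state
#' the diagonal blocks (kinetic plus one-body potential per mode, two-body
#' potential per mode pair) and for each coupling pair the potential-only
#' blocks.  Constant terms are carried through unchanged.
#'
#' @param model a `vibronic_model`.
#' @param bases list of `modal_basis`, one per mode.
#' @param check_convergence,conv_tol forwarded to the integral routines.
#' @return a list of class `integral_table` with elements `diag[[alpha]]` and
#'   `offdiag[["a,b"]]`, each containing `F0`, `one` (per-mode matrices) and
#'   `two` (per-pair arrays), plus provenance metadata.
#' @export
compute_integral_tables <- function(model, bases,
                                    check_convergence = FALSE, conv_tol = 1e-8) {
  stopifnot(inherits(model, "vibronic_model"), length(bases) == model$M)
  blocks <- function(f, kinetic) {
    one <- vector("list", model$M)
    for (i in seq_len(model$M)) {
      t1 <- f$one[[as.character(i)]]
      if (is.null(t1) && !kinetic) next
      one[[i]] <- one_body_integrals(bases[[i]], t1, include_kinetic = kinetic,
                                     check_convergence = check_convergence,
                                     conv_tol = conv_tol)
    }
    two <- list()
    for (nm in names(f$two)) {
      p <- as.integer(strsplit(nm, ",")[[1]])
      two[[nm]] <- two_body_integrals(bases[[p[1]]], bases[[p[2]]], f$two[[nm]],
                                      check_convergence = check_convergence,
                                      conv_tol = conv_tol)
    }
    list(F0 = f$F0, one = one, two = two)
  }
  out <- list(diag = lapply(model$diag, blocks, kinetic = TRUE),
              offdiag = lapply(model$offdiag, blocks, kinetic = FALSE),
              meta = list(N = vapply(bases, function(b) b$N, integer(1)),
                          basis_types = vapply(bases, function(b) b$spec$type, character(1))))
  class(out) <- "integral_table"
  out
}
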