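# Dense reference implementation: builds the full direct-product vibronic
# Hamiltonian from the same second-quantized term list and propagates it
# exactly by eigendecomposition.  Used as the verification oracle for every
# tensor-network result at desk scale.

#' Dense vibronic system
#'
#' Builds the full `D x D` Hamiltonian matrix (`D = n_el * prod(N)`) from a
#' second-quantized term list.  Basis enumeration is lexicographic in
#' `(gamma, n_1, ..., n_M)` with the last mode index fastest; `n_i` is the
#' zero-based occupation (modal quantum number) of mode `i`.
#'
#' @param sqh an `sq_hamiltonian`.
#' @param dim_cap refuse dimensions above this cap unless overridden.
#' @return an object of class `dense_system` with fields `H`, `dim`, `n_el`,
#'   `N` and `strides`.
#' @export
build_dense <- function(sqh, dim_cap = 20000L) {
  stopifnot(inherits(sqh, "sq_hamiltonian"))
  N <- sqh$N; M <- sqh$M
  Dv <- prod(N)
  if (!length(N)) Dv <- 1L
  D <- sqh$n_el * Dv
  if (D > dim_cap) stop(sprintf("dense dimension %d exceeds cap %d", D, dim_cap))
  # strides for zero-based occupations, mode M fastest
  strides <- if (M) rev(cumprod(rev(c(N[-1], 1L)))) else integer()
  H <- matrix(0, D, D)
  tm <- sqh$terms
  # offsets over the unconstrained modes, cached per mode subset
  off_cache <- new.env(parent = emptyenv())
  free_offsets <- function(fixed) {
    key <- paste0("k", paste(fixed, collapse = ","))
    if (!is.null(off_cache[[key]])) return(off_cache[[key]])
    free <- setdiff(seq_len(M), fixed)
    off <- 0L
    for (i in free) off <- as.vector(outer(off, (seq_len(N[i]) - 1L) * strides[i], `+`))
    off_cache[[key]] <- off
    off
  }
  for (t in seq_len(nrow(tm))) {
    a <- tm$a[t]; b <- tm$b[t]; c0 <- tm$coeff[t]
    fixed <- integer(); row0 <- 0L; col0 <- 0L
    if (!is.na(tm$i1[t])) {
      fixed <- tm$i1[t]
      row0 <- row0 + (tm$k1[t] - 1L) * strides[tm$i1[t]]
      col0 <- col0 + (tm$h1[t] - 1L) * strides[tm$i1[t]]
    }
    if (!is.na(tm$i2[t])) {
      fixed <- c(fixed, tm$i2[t])
      row0 <- row0 + (tm$k2[t] - 1L) * strides[tm$i2[t]]
      col0 <- col0 + (tm$h2[t] - 1L) * strides[tm$i2[t]]
    }
    off <- free_offsets(fixed)
    rows <- (a - 1L) * Dv + row0 + off + 1L
    cols <- (b - 1L) * Dv + col0 + off + 1L
    idx <- cbind(rows, cols)
    H[idx] <- H[idx] + c0
  }
  structure(list(H = H, dim = D, n_el = sqh$n_el, N = N, Dv = Dv,
                 strides = strides),
            class = "dense_system")
}

#' @export
print.dense_system <- function(x, ...) {
  cat(sprintf("<dense_system> dim %d (%d states x %d vibrational configs)\n",
              x$dim, x$n_el, x$Dv))
  invisible(x)
}

#' Dense basis index of a configuration
#'
#' @param sys a `dense_system`.
#' @param gamma electronic state (1-based).
#' @param occ zero-based modal occupations, length `M`.
#' @return 1-based index into the dense basis.
#' @export
dense_index <- function(sys, gamma, occ = integer()) {
  stopifnot(gamma >= 1, gamma <= sys$n_el, length(occ) == length(sys$N))
  as.integer((gamma - 1L) * sys$Dv + sum(occ * sys$strides) + 1L)
}

#' Exact propagation of a dense system
#'
#' Propagates an initial vector with the eigendecomposition propagator
#' `psi(t) = U exp(-i E t) U^T psi(0)` and returns states, the
#' autocorrelation `C(t) = <psi(0)|psi(t)>` and diabatic populations.
#'
#' @param sys a `dense_system`.
#' @param v0 normalized initial vector (length `sys$dim`).
#' @param times numeric vector of times (a.u.).
#' @return list with `times`, `states` (`dim x length(times)` complex
#'   matrix), `autocorr`, and `populations`
#'   (`length(times) x n_el` matrix).
#' @export
dense_propagate <- function(sys, v0, times) {
  stopifnot(length(v0) == sys$dim)
  nrm <- sqrt(sum(Mod(v0)^2))
  if (abs(nrm - 1) > 1e-8) stop("initial vector must be normalized")
  ee <- eigen(sys$H, symmetric = TRUE)
  aa <- crossprod(ee$vectors, v0)        # complex amplitudes
  phases <- exp(outer(ee$values, times, function(E, t) -1i * E * t))
  states <- ee$vectors %*% (phases * as.vector(aa))
  C <- as.vector(crossprod(Conj(v0), states))
  pops <- matrix(0, length(times), sys$n_el)
  for (g in seq_len(sys$n_el)) {
    rows <- ((g - 1L) * sys$Dv + 1L):(g * sys$Dv)
    pops[, g] <- colSums(Mod(states[rows, , drop = FALSE])^2)
  }
  list(times = times, states = states, autocorr = C, populations = pops,
       eigenvalues = ee$values)
}

#' Ground-state energy of a dense system
#' @param sys a `dense_system`.
#' @return lowest eigenvalue of the Hamiltonian.
#' @export
dense_ground_energy <- function(sys) {
  min(eigen(sys$H, symmetric = TRUE, only.values = TRUE)$values)
}
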