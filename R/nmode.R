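# n-mode expansion machinery: term specifications, NModeFunction containers,
# vibronic models.  A surface F(Q) over M mass-weighted modes is stored as
#   F(Q) = F0 + sum_i F1[i](Q_i) + sum_{i<j} F2[ij](Q_i,Q_j) + ...
# Each one- or two-body term is a declarative spec (polynomial, Morse,
# tabulated grid, separable product, or an opaque R function) so that models
# round-trip through plain-text files.

#' One-dimensional expansion term
#'
#' Declarative specification of a one-body term of an n-mode expansion.
#' Supported types: `"poly"` (coefficients `coef[k+1]` of `Q^k`), `"morse"`
#' (`D*(1-exp(-a*(Q-Q0)))^2`), `"grid"` (tabulated values, natural cubic
#' spline interpolation), and `"func"` (arbitrary vectorized R function;
#' not serializable to model files).
#'
#' @param coef numeric coefficient vector, constant term first.
#' @param D,a,Q0 Morse well depth (hartree), range parameter and minimum.
#' @param Q,V grid nodes and tabulated values.
#' @param f vectorized function of one coordinate.
#' @return an object of class `nm_term`.
#' @export
nm_poly <- function(coef) {
  stopifnot(is.numeric(coef), length(coef) >= 1, all(is.finite(coef)))
  structure(list(type = "poly", coef = as.numeric(coef)), class = "nm_term")
}

#' @rdname nm_poly
#' @export
nm_morse <- function(D, a, Q0 = 0) {
  stopifnot(is.finite(D), D > 0, is.finite(a), a != 0, is.finite(Q0))
  structure(list(type = "morse", D = D, a = a, Q0 = Q0), class = "nm_term")
}

#' @rdname nm_poly
#' @export
nm_grid <- function(Q, V) {
  stopifnot(length(Q) == length(V), length(Q) >= 4, !is.unsorted(Q))
  structure(list(type = "grid", Q = as.numeric(Q), V = as.numeric(V)),
            class = "nm_term")
}

#' @rdname nm_poly
#' @export
nm_func <- function(f) {
  stopifnot(is.function(f))
  structure(list(type = "func", f = f), class = "nm_term")
}

#' Two-dimensional expansion term
#'
#' Declarative specification of a two-body term. Types: `"poly2"`
#' (`sum_{pq} coef[p+1,q+1] Qi^p Qj^q`), `"sprod"` (separable product
#' `f1(Qi)*f2(Qj)` of two one-dimensional terms), `"func2"` (arbitrary
#' function of two coordinates).
#'
#' @param coef coefficient matrix, `coef[p+1, q+1]` multiplying `Qi^p Qj^q`.
#' @param f1,f2 one-dimensional `nm_term` factors.
#' @param f vectorized function `f(Qi, Qj)`.
#' @return an object of class `nm_term2`.
#' @export
nm_poly2 <- function(coef) {
  coef <- as.matrix(coef)
  stopifnot(is.numeric(coef), all(is.finite(coef)))
  structure(list(type = "poly2", coef = coef), class = "nm_term2")
}

#' @rdname nm_poly2
#' @export
nm_sprod <- function(f1, f2) {
  stopifnot(inherits(f1, "nm_term"), inherits(f2, "nm_term"))
  structure(list(type = "sprod", f1 = f1, f2 = f2), class = "nm_term2")
}

#' @rdname nm_poly2
#' @export
nm_func2 <- function(f) {
  stopifnot(is.function(f))
  structure(list(type = "func2", f = f), class = "nm_term2")
}

#' Evaluate a one-dimensional term on a vector of coordinates
#' @param term an `nm_term`.
#' @param Q numeric vector of coordinates.
#' @return numeric vector of values.
#' @export
nm_eval1 <- function(term, Q) {
  stopifnot(inherits(term, "nm_term"))
  switch(term$type,
    poly = {
      v <- rep(term$coef[length(term$coef)], length(Q))
      if (length(term$coef) > 1)
        for (k in seq(length(term$coef) - 1L, 1L)) v <- v * Q + term$coef[k]
      v
    },
    morse = term$D * (1 - exp(-term$a * (Q - term$Q0)))^2,
    grid = stats::splinefun(term$Q, term$V, method = "natural")(Q),
    func = {
      v <- term$f(Q)
      stopifnot(length(v) == length(Q))
      as.numeric(v)
    },
    stop("unknown nm_term type: ", term$type)
  )
}

#' Evaluate a two-dimensional term on the outer grid of two coordinate vectors
#' @param term an `nm_term2`.
#' @param Q1,Q2 coordinate vectors; result is the `length(Q1) x length(Q2)`
#'   matrix of values `term(Q1[g1], Q2[g2])`.
#' @return numeric matrix.
#' @export
nm_eval2 <- function(term, Q1, Q2) {
  stopifnot(inherits(term, "nm_term2"))
  switch(term$type,
    poly2 = {
      P1 <- outer(Q1, 0:(nrow(term$coef) - 1L), `^`)
      P2 <- outer(Q2, 0:(ncol(term$coef) - 1L), `^`)
      P1 %*% term$coef %*% t(P2)
    },
    sprod = outer(nm_eval1(term$f1, Q1), nm_eval1(term$f2, Q2)),
    func2 = outer(Q1, Q2, term$f),
    stop("unknown nm_term2 type: ", term$type)
  )
}

.as_term1 <- function(x) {
  if (inherits(x, "nm_term")) x else if (is.function(x)) nm_func(x)
  else stop("one-body terms must be nm_term objects or functions")
}
.as_term2 <- function(x) {
  if (inherits(x, "nm_term2")) x else if (is.function(x)) nm_func2(x)
  else stop("two-body terms must be nm_term2 objects or functions")
}

#' n-mode expansion of a multidimensional function
#'
#' Container for the n-mode expansion
#' `F(Q) = F0 + sum_i F1[i](Q_i) + sum_{i<j} F2[ij](Q_i, Q_j) + ...`
#' of a potential energy surface or coupling surface over `M` mass-weighted
#' modes.  One-body terms are keyed by mode index, two-body terms by the
#' strictly ordered pair `"i,j"` with `i < j`.  Three-body terms are accepted
#' as a structural hook (keys `"i,j,k"`, function type only).
#'
#' @param M number of modes (>= 0).
#' @param F0 constant term (hartree); carries vertical electronic energies
#'   and constant couplings.
#' @param one named list of one-body terms; names are mode indices `"1"`..`"M"`.
#' @param two named list of two-body terms; names `"i,j"` with `i < j`.
#' @param three named list of three-body function terms (hook).
#' @return an object of class `nmode_function`.
#' @export
nmode_function <- function(M, F0 = 0, one = list(), two = list(), three = list()) {
  M <- as.integer(M)
  stopifnot(M >= 0, is.finite(F0))
  if (length(one)) {
    idx <- as.integer(names(one))
    if (anyNA(idx) || any(idx < 1L | idx > M)) stop("one-body mode indices must lie in 1..M")
    if (anyDuplicated(idx)) stop("duplicate one-body mode index")
    one <- lapply(one, .as_term1)
  }
  if (length(two)) {
    prs <- lapply(strsplit(names(two), ","), as.integer)
    ok <- vapply(prs, function(p) length(p) == 2L && !anyNA(p) &&
                   p[1] >= 1L && p[2] <= M && p[1] < p[2], logical(1))
    if (!all(ok)) stop("two-body keys must be 'i,j' with 1 <= i < j <= M")
    if (anyDuplicated(names(two))) stop("duplicate two-body pair")
    two <- lapply(two, .as_term2)
  }
  order <- if (length(three)) 3L else if (length(two)) 2L else if (length(one)) 1L else 0L
  structure(list(M = M, F0 = F0, one = one, two = two, three = three,
                 order = order),
            class = "nmode_function")
}

#' Evaluate an n-mode expansion at a point
#'
#' Sums the stored constant, one-body, two-body (and three-body, if present)
#' contributions at a single point in mode space.
#'
#' @param f an `nmode_function`.
#' @param Q numeric vector with exactly `f$M` coordinates.
#' @return scalar value of the expansion at `Q`.
#' @export
evaluate_nmode <- function(f, Q) {
  stopifnot(inherits(f, "nmode_function"))
  if (length(Q) != f$M)
    stop(sprintf("dimension mismatch: expected %d coordinates, got %d", f$M, length(Q)))
  v <- f$F0
  for (nm in names(f$one)) {
    i <- as.integer(nm)
    v <- v + nm_eval1(f$one[[nm]], Q[i])
  }
  for (nm in names(f$two)) {
    p <- as.integer(strsplit(nm, ",")[[1]])
    v <- v + nm_eval2(f$two[[nm]], Q[p[1]], Q[p[2]])[1, 1]
  }
  for (nm in names(f$three)) {
    p <- as.integer(strsplit(nm, ",")[[1]])
    t3 <- f$three[[nm]]
    fn <- if (is.function(t3)) t3 else t3$f
    v <- v + fn(Q[p[1]], Q[p[2]], Q[p[3]])
  }
  v
}

#' Multi-state vibronic model
#'
#' A block vibronic Hamiltonian over `n_el` diabatic electronic states and
#' `M` vibrational modes: diagonal blocks are vibrational Hamiltonians
#' `T + v_alpha(Q)` with the potential given as an n-mode expansion
#' (including the vertical electronic energy as its constant term), and
#' off-diagonal blocks are real nonadiabatic coupling surfaces `V_ab(Q)`,
#' stored once per unordered state pair and applied Hermitianly.
#' The kinetic operator is `-1/2 d^2/dQ_i^2` per mass-weighted mode.
#'
#' @param freqs_cm per-mode reference harmonic frequencies (cm^-1); used for
#'   default basis construction and grid bounds.
#' @param diag list of `nmode_function` potentials, one per electronic state.
#' @param offdiag named list of `nmode_function` couplings keyed `"a,b"` with
#'   `a < b` (applied symmetrically to the `(b,a)` block).
#' @param meta optional free-form metadata list.
#' @return an object of class `vibronic_model`.
#' @export
vibronic_model <- function(freqs_cm, diag, offdiag = list(), meta = list()) {
  M <- length(freqs_cm)
  stopifnot(M == 0 || all(freqs_cm > 0))
  n_el <- length(diag)
  stopifnot(n_el >= 1)
  for (f in diag) {
    stopifnot(inherits(f, "nmode_function"))
    if (f$M != M) stop("diagonal n-mode function has wrong mode count")
  }
  if (length(offdiag)) {
    prs <- lapply(strsplit(names(offdiag), ","), as.integer)
    ok <- vapply(prs, function(p) length(p) == 2L && !anyNA(p) &&
                   p[1] >= 1L && p[2] <= n_el && p[1] < p[2], logical(1))
    if (!all(ok)) stop("coupling keys must be 'a,b' with 1 <= a < b <= n_el")
    for (f in offdiag) {
      stopifnot(inherits(f, "nmode_function"))
      if (f$M != M) stop("coupling n-mode function has wrong mode count")
    }
  }
  structure(list(n_el = n_el, M = M,
                 freqs_cm = as.numeric(freqs_cm),
                 omega = cm_to_au(as.numeric(freqs_cm)),
                 diag = diag, offdiag = offdiag, meta = meta),
            class = "vibronic_model")
}

#' @export
print.vibronic_model <- function(x, ...) {
  cat(sprintf("<vibronic_model> %d electronic state(s), %d mode(s)\n", x$n_el, x$M))
  if (x$M) cat("  frequencies (cm^-1):", paste(signif(x$freqs_cm, 6), collapse = ", "), "\n")
  cat(sprintf("  couplings: %d state pair(s)\n", length(x$offdiag)))
  invisible(x)
}

#' Transition dipole model
#'
#' n-mode representation of the transition dipole surface.  Only the constant
#' (Condon) term `mu0` is used by the excitation machinery; coordinate
#' dependence can be stored as an `nmode_function` hook but is not applied.
#'
#' @param mu0 constant transition dipole (a.u.).
#' @param higher optional `nmode_function` with coordinate-dependent terms.
#' @return an object of class `dipole_model`.
#' @export
dipole_model <- function(mu0 = 1, higher = NULL) {
  stopifnot(is.finite(mu0))
  if (!is.null(higher)) stopifnot(inherits(higher, "nmode_function"))
  structure(list(mu0 = mu0, higher = higher), class = "dipole_model")
}

#' Displaced harmonic oscillator benchmark model
#'
#' One excited electronic state and one mode with the excited potential
#' `v(Q) = 0.5*omega^2*(Q-d)^2 + dE` relative to a ground state of frequency
#' `omega` centered at the origin.  The Huang-Rhys factor `S = omega*d^2/2`
#' is recorded in the metadata; the model has the analytic Franck-Condon
#' progression with Poisson intensities `exp(-S) S^n / n!`.
#'
#' @param omega harmonic frequency (a.u. unless `units = "cm"`).
#' @param d mass-weighted displacement of the excited minimum.
#' @param dE vertical shift of the excited minimum (hartree).
#' @param units `"au"` or `"cm"` for `omega`.
#' @return a `vibronic_model` with one state and one mode.
#' @export
make_displaced_ho_model <- function(omega, d, dE = 0, units = c("au", "cm")) {
  units <- match.arg(units)
  w <- if (units == "cm") cm_to_au(omega) else omega
  if (!is.finite(w) || w <= 0) stop("omega must be positive")
  v1 <- nm_poly(c(0.5 * w^2 * d^2, -w^2 * d, 0.5 * w^2))
  pes <- nmode_function(1L, F0 = dE, one = list("1" = v1))
  vibronic_model(freqs_cm = au_to_cm(w), diag = list(pes),
                 meta = list(kind = "displaced_ho", omega = w, d = d, dE = dE,
                             huang_rhys = w * d^2 / 2))
}

#' Coupled two-state model
#'
#' Convenience constructor for a two-state vibronic model with per-state
#' n-mode diagonal potentials (polynomial, Morse, or tabulated) and a
#' user-supplied off-diagonal coupling surface.
#'
#' @param freqs_cm per-mode reference frequencies (cm^-1).
#' @param state1,state2 `nmode_function` potentials for the two states.
#' @param coupling `nmode_function` coupling between them.
#' @param meta optional metadata.
#' @return a `vibronic_model` with two states.
#' @export
make_coupled_two_state_model <- function(freqs_cm, state1, state2, coupling,
                                         meta = list()) {
  stopifnot(inherits(coupling, "nmode_function"))
  vibronic_model(freqs_cm, diag = list(state1, state2),
                 offdiag = list("1,2" = coupling), meta = meta)
}

#' Seeded random anharmonic multi-state model
#'
#' Generates a reproducible two-state (by default) model of the
#' displaced/Morse-distorted few-mode type used for verification against the
#' dense oracle.  Each state's potential per mode is a displaced harmonic
#' well with a small cubic/quartic distortion, expressed in the dimensionless
#' coordinate `u = sqrt(omega) Q`; diagonal two-body terms are bilinear, and
#' the interstate coupling has a constant part plus linear terms in every
#' mode.  All magnitudes are drawn at chemically sensible scales
#' (frequencies 800-1800 cm^-1, dimensionless displacements below ~0.8,
#' couplings of a few millihartree).
#'
#' @param M number of modes.
#' @param seed integer seed; the model is a deterministic function of it.
#' @param n_el number of electronic states (couplings between all pairs).
#' @param two_body include bilinear diagonal two-body terms?
#' @return a `vibronic_model`.
#' @export
random_vibronic_model <- function(M, seed, n_el = 2L, two_body = TRUE) {
  stopifnot(M >= 1, n_el >= 2)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  freqs_cm <- sort(stats::runif(M, 800, 1800))
  w <- cm_to_au(freqs_cm)
  # polynomial in u = sqrt(w) Q with energy scale w  ->  polynomial in Q
  u_poly <- function(omega, cu) nm_poly(omega * cu * omega^((seq_along(cu) - 1) / 2))
  diag <- vector("list", n_el)
  for (a in seq_len(n_el)) {
    one <- list()
    for (i in seq_len(M)) {
      s  <- stats::runif(1, 0.9, 1.1)          # frequency scaling
      dl <- if (a == 1) 0 else stats::runif(1, -0.8, 0.8)  # dimensionless displacement
      a3 <- if (a == 1) 0 else stats::runif(1, -0.02, 0.02)
      a4 <- stats::runif(1, 0.002, 0.01)
      # 0.5 s^2 (u - dl)^2 + a3 u^3 + a4 u^4  (units of w)
      cu <- c(0.5 * s^2 * dl^2, -s^2 * dl, 0.5 * s^2, a3, a4)
      one[[as.character(i)]] <- u_poly(w[i], cu)
    }
    two <- list()
    if (two_body && M >= 2) {
      for (i in seq_len(M - 1)) for (j in seq(i + 1, M)) {
        kap <- stats::runif(1, -0.03, 0.03) * sqrt(w[i] * w[j])
        two[[paste0(i, ",", j)]] <-
          nm_sprod(nm_poly(c(0, kap * sqrt(w[i]))), nm_poly(c(0, sqrt(w[j]))))
      }
    }
    E0 <- if (a == 1) 0 else 0.01 * (a - 1) + stats::runif(1, -0.002, 0.002)
    diag[[a]] <- nmode_function(M, F0 = E0, one = one, two = two)
  }
  offdiag <- list()
  for (a in seq_len(n_el - 1)) for (b in seq(a + 1, n_el)) {
    lam0 <- stats::runif(1, 5e-4, 3e-3)
    one <- list()
    for (i in seq_len(M)) {
      li <- stats::runif(1, -2e-3, 2e-3)
      one[[as.character(i)]] <- nm_poly(c(0, li * sqrt(w[i])))
    }
    offdiag[[paste0(a, ",", b)]] <- nmode_function(M, F0 = lam0, one = one)
  }
  vibronic_model(freqs_cm, diag, offdiag,
                 meta = list(kind = "random", seed = as.integer(seed)))
}
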