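# Vibronic matrix product states.  The lattice places the N_el electronic
# sites (physical dimension 2, occupations 0/1) at the head of the chain,
# followed by one site per vibrational mode with physical dimension N_i
# (the modal quantum numbers 0..N_i-1; composite operators make an auxiliary
# vacuum level unnecessary).  Electronic particle number is a U(1) symmetry:
# every bond index carries the cumulative electronic occupation to its left,
# site tensors are nonzero only on charge-consistent blocks, and all
# factorizations (QR, SVD) are performed sector by sector so the block
# structure is preserved exactly.

#' Vibronic MPS lattice specification
#'
#' @param n_el number of electronic states (one head site each).
#' @param N integer vector of vibrational basis sizes, one per mode
#'   (modes are placed after the electronic sites in ascending frequency
#'   order by convention).
#' @return an object of class `vib_lattice`.
#' @export
mps_lattice <- function(n_el, N = integer()) {
  n_el <- as.integer(n_el); N <- as.integer(N)
  stopifnot(n_el >= 1, all(N >= 1))
  dims <- c(rep(2L, n_el), N)
  charges <- c(rep(list(c(0L, 1L)), n_el), lapply(N, function(n) rep(0L, n)))
  structure(list(n_el = n_el, N = N, M = length(N), L = n_el + length(N),
                 dims = dims, charges = charges),
            class = "vib_lattice")
}

#' @export
print.vib_lattice <- function(x, ...) {
  cat(sprintf("<vib_lattice> %d electronic + %d vibrational sites, dims [%s]\n",
              x$n_el, x$M, paste(x$dims, collapse = ",")))
  invisible(x)
}

.lattice_of <- function(x) {
  if (inherits(x, "vib_lattice")) return(x)
  if (inherits(x, "sq_hamiltonian")) return(mps_lattice(x$n_el, x$N))
  stop("cannot derive a lattice from ", class(x)[1])
}

# number of product states of sites 1..b (left) / b+1..L (right) per charge
lattice_capacities <- function(lat, total_charge = 1L) {
  left <- vector("list", lat$L + 1L)
  left[[1]] <- c("0" = 1)
  for (s in seq_len(lat$L)) {
    acc <- numeric()
    prev <- left[[s]]
    for (qn in names(prev)) for (c in unique(lat$charges[[s]])) {
      mult <- sum(lat$charges[[s]] == c)
      key <- as.character(as.integer(qn) + c)
      acc[key] <- (if (key %in% names(acc)) acc[[key]] else 0) + prev[[qn]] * mult
    }
    left[[s + 1L]] <- acc
  }
  right <- vector("list", lat$L + 1L)
  right[[lat$L + 1L]] <- stats::setNames(1, as.character(total_charge))
  for (s in seq(lat$L, 1L)) {
    acc <- numeric()
    nxt <- right[[s + 1L]]
    for (qn in names(nxt)) for (c in unique(lat$charges[[s]])) {
      mult <- sum(lat$charges[[s]] == c)
      key <- as.character(as.integer(qn) - c)
      acc[key] <- (if (key %in% names(acc)) acc[[key]] else 0) + nxt[[qn]] * mult
    }
    right[[s]] <- acc
  }
  list(left = left, right = right)
}

.new_mps <- function(lattice, tensors, bond_q, center = NA_integer_) {
  structure(list(lattice = lattice, A = tensors, bq = bond_q,
                 center = as.integer(center)),
            class = "vibronic_mps")
}

#' @export
print.vibronic_mps <- function(x, ...) {
  cat(sprintf("<vibronic_mps> %d sites, bond dims [%s], charge %d, center %s\n",
              x$lattice$L, paste(mps_bond_dims(x), collapse = ","),
              mps_total_charge(x),
              if (is.na(x$center)) "unset" else x$center))
  invisible(x)
}

#' Bond dimensions of an MPS
#' @param psi a `vibronic_mps`.
#' @return integer vector of the `L - 1` internal bond dimensions.
#' @export
mps_bond_dims <- function(psi) {
  L <- psi$lattice$L
  if (L < 2) return(integer())
  vapply(seq_len(L - 1L), function(b) dim(psi$A[[b]])[3], integer(1))
}

#' Total U(1) charge (electronic occupation) of an MPS
#' @param psi a `vibronic_mps`.
#' @return integer total charge.
#' @export
mps_total_charge <- function(psi) as.integer(psi$bq[[psi$lattice$L + 1L]][1])

#' Product state on the vibronic lattice
#'
#' Bond-dimension-1 MPS with electronic state `gamma` occupied (or no state
#' occupied for `gamma = 0`, the electronic vacuum reference) and each mode
#' in a single modal basis function.  With the ground-state modal basis, the
#' Condon initial wavepacket is `gamma = target`, all occupations 0.
#'
#' @param lattice a `vib_lattice` (or an `sq_hamiltonian` to take it from).
#' @param gamma electronic state index (1-based), or 0 for the vacuum.
#' @param occ zero-based modal occupations, length `M` (default all 0).
#' @return a normalized `vibronic_mps`.
#' @export
product_state <- function(lattice, gamma, occ = NULL) {
  lat <- .lattice_of(lattice)
  if (is.null(occ)) occ <- rep(0L, lat$M)
  stopifnot(length(occ) == lat$M)
  if (gamma < 0 || gamma > lat$n_el) stop("electronic index out of range")
  if (lat$M && (any(occ < 0) || any(occ >= lat$N))) stop("occupation out of range")
  tensors <- vector("list", lat$L)
  bq <- vector("list", lat$L + 1L)
  bq[[1]] <- 0L
  for (s in seq_len(lat$n_el)) {
    v <- array(0i, c(1L, 2L, 1L))
    v[1, if (s == gamma) 2L else 1L, 1] <- 1
    tensors[[s]] <- v
    bq[[s + 1L]] <- bq[[s]] + if (s == gamma) 1L else 0L
  }
  for (i in seq_len(lat$M)) {
    s <- lat$n_el + i
    v <- array(0i, c(1L, lat$N[i], 1L))
    v[1, occ[i] + 1L, 1] <- 1
    tensors[[s]] <- v
    bq[[s + 1L]] <- bq[[s]]
  }
  .new_mps(lat, tensors, bq, center = 1L)
}

#' Random U(1)-symmetric MPS
#'
#' Deterministic (seeded) random MPS in the sector of total electronic
#' charge `total_charge`, with bond dimensions capped at `m` and at the
#' exact sector capacities.  Entries outside charge-consistent blocks are
#' identically zero by construction.  The state is normalized with the
#' canonical center at site 1.
#'
#' @param lattice a `vib_lattice` (or `sq_hamiltonian`).
#' @param m maximum bond dimension.
#' @param seed integer seed.
#' @param total_charge U(1) sector (default 1, the excited manifold).
#' @return a `vibronic_mps`.
#' @export
random_mps <- function(lattice, m, seed, total_charge = 1L) {
  lat <- .lattice_of(lattice)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  cap <- lattice_capacities(lat, total_charge)
  bq <- vector("list", lat$L + 1L)
  bq[[1]] <- 0L
  bq[[lat$L + 1L]] <- as.integer(total_charge)
  for (b in seq_len(lat$L - 1L)) {
    ql <- cap$left[[b + 1L]]; qr <- cap$right[[b + 1L]]
    qs <- intersect(names(ql), names(qr))
    if (!length(qs)) stop("empty charge sector: lattice cannot carry this total charge")
    v <- integer()
    for (qn in qs) {
      dq <- min(ql[[qn]], qr[[qn]], m)
      v <- c(v, rep(as.integer(qn), dq))
    }
    bq[[b + 1L]] <- v
  }
  tensors <- vector("list", lat$L)
  for (s in seq_len(lat$L)) {
    dl <- length(bq[[s]]); d <- lat$dims[s]; dr <- length(bq[[s + 1L]])
    A <- array(0i, c(dl, d, dr))
    for (l in seq_len(dl)) for (x in seq_len(d)) {
      q <- bq[[s]][l] + lat$charges[[s]][x]
      hit <- which(bq[[s + 1L]] == q)
      if (length(hit))
        A[l, x, hit] <- stats::rnorm(length(hit)) + 1i * stats::rnorm(length(hit))
    }
    tensors[[s]] <- A
  }
  psi <- .new_mps(lat, tensors, bq, center = NA_integer_)
  psi <- canonicalize(psi, 1L)
  mps_scale(psi, 1 / mps_norm(psi))
}

# multiply the center tensor by a scalar
mps_scale <- function(psi, s) {
  c0 <- if (is.na(psi$center)) 1L else psi$center
  psi$A[[c0]] <- psi$A[[c0]] * s
  psi
}

#' Norm of an MPS
#' @param psi a `vibronic_mps`.
#' @return the 2-norm `sqrt(<psi|psi>)`.
#' @export
mps_norm <- function(psi) sqrt(Re(mps_overlap(psi, psi)))

#' Overlap of two MPSs
#'
#' `<phi|psi>` (conjugate-linear in the first argument) by transfer-matrix
#' contraction; the states must share a lattice but may differ in bond
#' dimensions and charge sectors.
#'
#' @param phi,psi `vibronic_mps` objects.
#' @return complex scalar.
#' @export
mps_overlap <- function(phi, psi) {
  if (!identical(phi$lattice$dims, psi$lattice$dims)) stop("lattice mismatch")
  T <- matrix(1 + 0i, 1, 1)
  for (s in seq_len(psi$lattice$L)) T <- transfer_step(T, psi$A[[s]], phi$A[[s]])
  T[1, 1]
}

#' Expectation value of an MPO
#'
#' Exact contraction `<psi| H |psi>`; real up to round-off for a Hermitian
#' operator.
#'
#' @param psi a `vibronic_mps`.
#' @param mpo a `vibronic_mpo` on the same lattice.
#' @return complex scalar (take `Re` for Hermitian operators).
#' @export
mps_expectation <- function(psi, mpo) {
  if (!identical(psi$lattice$dims, mpo$lattice$dims)) stop("lattice mismatch")
  L <- array(1 + 0i, c(1, 1, 1))
  for (s in seq_len(psi$lattice$L))
    L <- contract_env_left(L, psi$A[[s]], mpo$W[[s]], psi$A[[s]])
  L[1, 1, 1]
}

#' Expectation values of single-site operators
#'
#' Computes `<psi| O_s |psi>` for a set of local operators in one pass of
#' transfer matrices (the state need not be normalized; values are not
#' divided by the norm).
#'
#' @param psi a `vibronic_mps`.
#' @param ops named list mapping site index (as character) to a local
#'   operator matrix `O[so, si]`.
#' @return complex vector, one value per requested site, in input order.
#' @export
mps_site_expectations <- function(psi, ops) {
  L <- psi$lattice$L
  sites <- as.integer(names(ops))
  stopifnot(all(sites >= 1 & sites <= L))
  lefts <- vector("list", L + 1L)
  lefts[[1]] <- matrix(1 + 0i, 1, 1)
  for (s in seq_len(L)) lefts[[s + 1L]] <- transfer_step(lefts[[s]], psi$A[[s]])
  rights <- vector("list", L + 1L)
  rights[[L + 1L]] <- matrix(1 + 0i, 1, 1)
  for (s in seq(L, 1L)) {
    da <- dim(psi$A[[s]])
    # right transfer: R (rk x rb) -> (lk x lb)
    T1 <- .m(psi$A[[s]], da[1] * da[2]) %*% rights[[s + 1L]]   # (lk*si, rb)
    dim(T1) <- c(da[1], da[2], dim(rights[[s + 1L]])[2])
    T1 <- aperm(T1, c(2, 3, 1))                                # (si, rb, lk)
    Bm <- aperm(Conj(psi$A[[s]]), c(2, 3, 1))                  # (so, rb, lb)
    T2 <- crossprod(.m(Bm, da[2] * dim(rights[[s + 1L]])[2]),
                    .m(T1, da[2] * dim(rights[[s + 1L]])[2]))  # (lb, lk)
    rights[[s]] <- t(T2)
  }
  vapply(seq_along(sites), function(j) {
    s <- sites[j]
    Tm <- transfer_step(lefts[[s]], psi$A[[s]], psi$A[[s]], op = ops[[j]])
    sum(Tm * rights[[s + 1L]])
  }, complex(1))
}

# ---- sector-wise factorizations ----------------------------------------

# QR of M grouped by row charges; columns acquire the row-sector charge.
# Returns Q (nrow x r), R (r x ncol(M) original columns), bond charges.
.sector_qr <- function(M, row_q) {
  qs <- sort(unique(row_q))
  Qs <- matrix(0i, nrow(M), 0); Rs <- matrix(0i, 0, ncol(M)); cq <- integer()
  for (q in qs) {
    rows <- which(row_q == q)
    sub <- M[rows, , drop = FALSE]
    if (max(Mod(sub)) == 0) next
    dec <- qr(sub)
    r <- min(length(rows), ncol(M))
    Qq <- qr.Q(dec); Rq <- qr.R(dec)[seq_len(r), , drop = FALSE]
    if (!is.null(dec$pivot)) Rq <- Rq[, order(dec$pivot), drop = FALSE]
    Qfull <- matrix(0i, nrow(M), r)
    Qfull[rows, ] <- Qq[, seq_len(r), drop = FALSE]
    Qs <- cbind(Qs, Qfull)
    Rs <- rbind(Rs, Rq)
    cq <- c(cq, rep(q, r))
  }
  if (!length(cq)) { # zero matrix: keep a single null column to stay shaped
    Qs <- matrix(0i, nrow(M), 1); Qs[1] <- 1
    Rs <- matrix(0i, 1, ncol(M)); cq <- row_q[1]
  }
  list(Q = Qs, R = Rs, charges = cq)
}

# sector-wise SVD of the two-site tensor matrix M (rows: left x phys1,
# cols: phys2 x right).  row_q / col_q give the U(1) charge each row/column
# carries into the new bond.  Keeps at most m_max singular values overall
# (descending), drops relative squared weight below cutoff, zeroes
# charge-inconsistent blocks (exact zeros analytically).
.sector_svd <- function(M, row_q, col_q, m_max = Inf, cutoff = 0) {
  qs <- intersect(unique(row_q), unique(col_q))
  pieces <- list()
  for (q in qs) {
    rows <- which(row_q == q); cols <- which(col_q == q)
    sub <- M[rows, cols, drop = FALSE]
    k <- min(length(rows), length(cols))
    sv <- svd(sub, nu = k, nv = k)
    pieces[[as.character(q)]] <- list(q = q, rows = rows, cols = cols,
                                      d = sv$d[seq_len(k)], u = sv$u, v = sv$v)
  }
  alld <- unlist(lapply(pieces, `[[`, "d"))
  if (!length(alld)) alld <- 0
  tot <- sum(alld^2)
  ord <- order(alld, decreasing = TRUE)
  keep_n <- min(length(ord), m_max)
  thresh <- if (tot > 0) sqrt(cutoff * tot) else 0
  kept <- ord[seq_len(keep_n)]
  kept <- kept[alld[kept] > thresh]
  if (!length(kept)) kept <- ord[1]
  keep_flag <- rep(FALSE, length(alld)); keep_flag[kept] <- TRUE
  discarded <- sum(alld[!keep_flag]^2)
  U <- matrix(0i, nrow(M), 0); Vh <- matrix(0i, 0, ncol(M))
  S <- numeric(); bq <- integer()
  off <- 0L
  for (p in pieces) {
    nk <- length(p$d)
    sel <- which(keep_flag[off + seq_len(nk)])
    off <- off + nk
    if (!length(sel)) next
    Ufull <- matrix(0i, nrow(M), length(sel)); Ufull[p$rows, ] <- p$u[, sel, drop = FALSE]
    Vfull <- matrix(0i, length(sel), ncol(M)); Vfull[, p$cols] <- Conj(t(p$v[, sel, drop = FALSE]))
    U <- cbind(U, Ufull); Vh <- rbind(Vh, Vfull)
    S <- c(S, p$d[sel]); bq <- c(bq, rep(p$q, length(sel)))
  }
  list(U = U, S = S, Vh = Vh, charges = bq, discarded = discarded)
}

# row charges of the (left x phys) unfolding of a site tensor
.row_charges <- function(psi, s) {
  ql <- psi$bq[[s]]; cs <- psi$lattice$charges[[s]]
  as.vector(outer(ql, cs, `+`))
}
# column charges of the (phys x right) unfolding (charge flowing into bond s)
.col_charges <- function(psi, s) {
  qr <- psi$bq[[s + 1L]]; cs <- psi$lattice$charges[[s]]
  as.vector(outer(-cs, qr, `+`))
}

#' Canonicalize an MPS
#'
#' Brings the state to mixed-canonical form with the orthogonality center at
#' the requested site: tensors left of the center are left-orthogonal,
#' tensors right of it right-orthogonal.  All factorizations are done per
#' charge sector.
#'
#' @param psi a `vibronic_mps`.
#' @param center target center site.
#' @return the canonicalized `vibronic_mps`.
#' @export
canonicalize <- function(psi, center = 1L) {
  L <- psi$lattice$L
  stopifnot(center >= 1, center <= L)
  from_l <- if (is.na(psi$center)) 1L else psi$center
  if (from_l < center) {
    for (s in seq(from_l, center - 1L)) {
      da <- dim(psi$A[[s]])
      dec <- .sector_qr(.m(psi$A[[s]], da[1] * da[2]), .row_charges(psi, s))
      psi$A[[s]] <- array(dec$Q, c(da[1], da[2], length(dec$charges)))
      psi$bq[[s + 1L]] <- dec$charges
      nxt <- psi$A[[s + 1L]]; dn <- dim(nxt)
      nxt <- dec$R %*% .m(nxt, dn[1])
      psi$A[[s + 1L]] <- array(nxt, c(length(dec$charges), dn[2], dn[3]))
    }
  }
  from_r <- if (is.na(psi$center)) L else psi$center
  if (from_r > center) {
    for (s in seq(from_r, center + 1L)) {
      da <- dim(psi$A[[s]])
      M <- .m(psi$A[[s]], da[1])               # (l, d*r)
      # LQ via QR of the conjugate transpose, sectored by column charges
      dec <- .sector_qr(Conj(t(M)), .col_charges(psi, s))
      r <- length(dec$charges)
      B <- Conj(t(dec$Q))                       # (r, d*rold) rows orthonormal
      psi$A[[s]] <- array(B, c(r, da[2], da[3]))
      psi$bq[[s]] <- dec$charges
      Lm <- Conj(t(dec$R))                      # (l, r)
      prv <- psi$A[[s - 1L]]; dp <- dim(prv)
      prv <- .m(prv, dp[1] * dp[2]) %*% Lm
      psi$A[[s - 1L]] <- array(prv, c(dp[1], dp[2], r))
    }
  }
  psi$center <- as.integer(center)
  psi
}

#' Truncate an MPS to a maximum bond dimension
#'
#' Sweeps the orthogonality center across the chain, truncating every bond
#' by a sector-wise SVD: at most `m_max` singular values are kept per bond
#' (largest first, across sectors) and relative squared singular values
#' below `cutoff` are dropped.  Returns the truncated state and the total
#' discarded squared weight.
#'
#' @param psi a `vibronic_mps`.
#' @param m_max maximum bond dimension.
#' @param cutoff relative squared singular-value threshold (default 1e-12).
#' @param renormalize rescale the state back to its original norm?
#' @return list with elements `psi` and `discarded`.
#' @export
truncate_mps <- function(psi, m_max, cutoff = 1e-12, renormalize = TRUE) {
  L <- psi$lattice$L
  psi <- canonicalize(psi, 1L)
  nrm0 <- mps_norm(psi)
  disc <- 0
  for (s in seq_len(L - 1L)) {
    th <- bond_tensor(psi, s)
    sp <- split_bond(psi, s, th, m_max, cutoff, keep = "right")
    psi <- sp$psi; disc <- disc + sp$discarded
  }
  psi$center <- L
  if (renormalize) {
    n <- mps_norm(psi)
    if (n > 0) psi <- mps_scale(psi, nrm0 / n)
  }
  list(psi = psi, discarded = disc)
}

# two-site tensor at bond (s, s+1); requires center at s or s+1
bond_tensor <- function(psi, s) {
  A <- psi$A[[s]]; B <- psi$A[[s + 1L]]
  da <- dim(A); db <- dim(B)
  th <- .m(A, da[1] * da[2]) %*% .m(B, db[1])
  array(th, c(da[1], da[2], db[2], db[3]))
}

# split a two-site tensor back into site tensors at bond (s, s+1).
# keep = "right": A_s becomes left-canonical, center moves to s+1.
# keep = "left":  B_{s+1} becomes right-canonical, center moves to s.
split_bond <- function(psi, s, th, m_max = Inf, cutoff = 0, keep = c("right", "left")) {
  keep <- match.arg(keep)
  dt <- dim(th)
  row_q <- as.vector(outer(psi$bq[[s]], psi$lattice$charges[[s]], `+`))
  col_q <- as.vector(outer(-psi$lattice$charges[[s + 1L]], psi$bq[[s + 2L]], `+`))
  sv <- .sector_svd(.m(th, dt[1] * dt[2]), row_q, col_q, m_max, cutoff)
  r <- length(sv$S)
  if (keep == "right") {
    psi$A[[s]] <- array(sv$U, c(dt[1], dt[2], r))
    psi$A[[s + 1L]] <- array(sv$S * sv$Vh, c(r, dt[3], dt[4]))
    psi$center <- s + 1L
  } else {
    psi$A[[s]] <- array(sv$U %*% diag(sv$S, r), c(dt[1], dt[2], r))
    psi$A[[s + 1L]] <- array(sv$Vh, c(r, dt[3], dt[4]))
    psi$center <- s
  }
  psi$bq[[s + 1L]] <- sv$charges
  list(psi = psi, discarded = sv$discarded, S = sv$S)
}

#' Audit the U(1) block structure of an MPS
#'
#' Verifies that every tensor entry outside the charge-consistent blocks is
#' zero (to `tol`) and that bond charge labels are consistent with the
#' lattice.
#'
#' @param psi a `vibronic_mps`.
#' @param tol absolute tolerance for off-block entries.
#' @return the maximum off-block magnitude, invisibly; errors on violation.
#' @export
mps_charge_audit <- function(psi, tol = 1e-12) {
  worst <- 0
  for (s in seq_len(psi$lattice$L)) {
    A <- psi$A[[s]]; da <- dim(A)
    ql <- psi$bq[[s]]; cs <- psi$lattice$charges[[s]]; qr <- psi$bq[[s + 1L]]
    ok <- outer(outer(ql, cs, `+`), qr, `==`)
    bad <- max(c(0, Mod(A[!ok])))
    worst <- max(worst, bad)
  }
  if (worst > tol) stop(sprintf("charge-violating amplitude %.3g found", worst))
  invisible(worst)
}

#' Expand MPS bonds to their full sector capacity
#'
#' Pads every bond with orthonormal zero-weight states up to
#' `min(m_max, full sector rank)`, leaving the represented state unchanged.
#' With fully expanded bonds the two-site effective Hamiltonians act in
#' complete local bases, which makes tangent-space propagation exact up to
#' the local exponential tolerance.
#'
#' @param psi a `vibronic_mps`.
#' @param m_max cap on the expanded bond dimensions.
#' @return the expanded `vibronic_mps` (center at the last site).
#' @export
mps_expand_bonds <- function(psi, m_max = Inf) {
  lat <- psi$lattice
  L <- lat$L
  if (L < 2) return(psi)
  cap <- lattice_capacities(lat, mps_total_charge(psi))
  psi <- canonicalize(psi, 1L)
  for (s in seq_len(L - 1L)) {
    A <- psi$A[[s]]; da <- dim(A)
    row_q <- .row_charges(psi, s)
    dec <- .sector_qr(.m(A, da[1] * da[2]), row_q)
    ql <- cap$left[[s + 1L]]; qr <- cap$right[[s + 1L]]
    qs <- sort(as.integer(intersect(names(ql), names(qr))))
    Qcols <- list(); Rrows <- list(); charges <- integer()
    for (q in qs) {
      rows <- which(row_q == q)
      have <- which(dec$charges == q)
      tgt <- min(ql[[as.character(q)]], qr[[as.character(q)]], m_max, length(rows))
      Qq <- dec$Q[, have, drop = FALSE]
      if (tgt > length(have)) {
        # orthonormal complement within the sector rows
        base <- matrix(0i, nrow(dec$Q), length(rows))
        base[cbind(rows, seq_along(rows))] <- 1
        proj <- base - Qq %*% crossprod(Conj(Qq), base)
        cq <- qr(proj)
        extra <- qr.Q(cq)[, seq_len(tgt - length(have)), drop = FALSE]
        Qq <- cbind(Qq, extra)
      }
      Qcols[[length(Qcols) + 1L]] <- Qq
      Rq <- matrix(0i, ncol(Qq), ncol(dec$R))
      if (length(have)) Rq[seq_along(have), ] <- dec$R[have, , drop = FALSE]
      Rrows[[length(Rrows) + 1L]] <- Rq
      charges <- c(charges, rep(q, ncol(Qq)))
    }
    Qp <- do.call(cbind, Qcols); Rp <- do.call(rbind, Rrows)
    psi$A[[s]] <- array(Qp, c(da[1], da[2], length(charges)))
    psi$bq[[s + 1L]] <- charges
    nxt <- psi$A[[s + 1L]]; dn <- dim(nxt)
    psi$A[[s + 1L]] <- array(Rp %*% .m(nxt, dn[1]), c(length(charges), dn[2], dn[3]))
  }
  psi$center <- L
  psi
}

#' Dense state vector of an MPS in the oracle basis enumeration
#'
#' Contracts the MPS into a full complex vector indexed like
#' [build_dense()]: lexicographic `(gamma, n_1, ..., n_M)` with the last
#' mode fastest, restricted to the charge-1 electronic sector.  Amplitudes
#' outside that sector (multiply-occupied or empty electronic
#' configurations) must be zero and are checked.
#'
#' @param psi a `vibronic_mps` with total charge 1.
#' @return complex vector of length `n_el * prod(N)`.
#' @export
mps_dense_vector <- function(psi) {
  lat <- psi$lattice
  V <- matrix(1 + 0i, 1, 1)   # (configs so far, bond)
  for (s in seq_len(lat$L)) {
    A <- psi$A[[s]]; da <- dim(A)
    V <- V %*% .m(A, da[1])                 # (P, d*r)
    dim(V) <- c(nrow(V) * da[2], da[3])     # site s slowest... see mapping below
  }
  v <- as.vector(V)   # linear index: site 1 fastest
  dims <- lat$dims
  # map oracle index (gamma, n_1..n_M; n_M fastest) -> chain index (site1 fastest)
  Dv <- if (lat$M) prod(lat$N) else 1L
  out <- complex(lat$n_el * Dv)
  mult <- c(1, cumprod(dims))[seq_len(lat$L)]   # chain strides (site s fastest)
  occ_grid <- if (lat$M) {
    g <- do.call(expand.grid, rev(lapply(lat$N, function(n) 0:(n - 1))))
    as.matrix(g[, rev(seq_len(lat$M)), drop = FALSE])  # col i = n_i, n_M fastest
  } else matrix(0L, 1, 0)
  vib_off <- if (lat$M) as.vector(occ_grid %*% mult[lat$n_el + seq_len(lat$M)]) else 0L
  for (g in seq_len(lat$n_el)) {
    el_off <- mult[g]   # occupation 1 on site g
    out[(g - 1L) * Dv + seq_len(Dv)] <- v[1L + el_off + vib_off]
  }
  out
}
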