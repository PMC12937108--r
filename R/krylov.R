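# Lanczos iterations for the local problems of DMRG and TDVP: the action of
# the Hermitian effective Hamiltonian is supplied as a closure; the Krylov
# tridiagonal is diagonalized to evaluate matrix exponentials (time steps)
# or extremal Ritz pairs (ground-state microiterations).  Full
# reorthogonalization is used throughout (local dimensions are small).

# exp(tau * H) %*% v via Lanczos; tau may be complex (-1i*dt) or real
# (imaginary time).  Errors out if the Krylov space cap is hit before the
# error estimate drops below tol.
krylov_expm <- function(afun, v, tau, tol = 1e-10, maxk = 30L) {
  nrm <- sqrt(sum(Mod(v)^2))
  if (nrm == 0) return(v)
  n <- length(v)
  maxk <- min(maxk, n)
  V <- matrix(0i, n, maxk)
  V[, 1] <- v / nrm
  alpha <- numeric(maxk); beta <- numeric(maxk)
  y <- NULL
  for (j in seq_len(maxk)) {
    w <- afun(V[, j])
    alpha[j] <- Re(sum(Conj(V[, j]) * w))
    w <- w - alpha[j] * V[, j]
    if (j > 1) w <- w - beta[j - 1] * V[, j - 1]
    # full reorthogonalization
    w <- w - V[, seq_len(j), drop = FALSE] %*% crossprod(Conj(V[, seq_len(j), drop = FALSE]), w)
    b <- sqrt(sum(Mod(w)^2))
    Tj <- .tridiag(alpha[seq_len(j)], beta[seq_len(j - 1)])
    ee <- eigen(Tj, symmetric = TRUE)
    y <- ee$vectors %*% (exp(tau * ee$values) * ee$vectors[1, ])
    if (b < 1e-13 || b * abs(y[j]) * min(1, abs(tau)) < tol || j == n)
      return(as.vector(V[, seq_len(j), drop = FALSE] %*% (nrm * y)))
    if (j == maxk) break
    beta[j] <- b
    V[, j + 1] <- w / b
  }
  stop(sprintf(
    "Krylov exponential did not converge: cap %d reached, error estimate %.3g (tol %.3g)",
    maxk, beta[maxk - 1] * abs(y[maxk]), tol))
}

.tridiag <- function(a, b) {
  n <- length(a)
  Tj <- diag(a, n)
  if (n > 1) for (i in seq_len(n - 1)) { Tj[i, i + 1] <- b[i]; Tj[i + 1, i] <- b[i] }
  Tj
}

# lowest Ritz pair of a Hermitian operator by restarted Lanczos
lanczos_ground <- function(afun, v0, tol = 1e-9, block = 40L, restarts = 20L) {
  n <- length(v0)
  v <- v0 / sqrt(sum(Mod(v0)^2))
  lam <- NA_real_
  for (r in seq_len(restarts)) {
    m <- min(block, n)
    V <- matrix(0i, n, m)
    V[, 1] <- v
    alpha <- numeric(m); beta <- numeric(m)
    k <- m
    for (j in seq_len(m)) {
      w <- afun(V[, j])
      alpha[j] <- Re(sum(Conj(V[, j]) * w))
      w <- w - alpha[j] * V[, j]
      if (j > 1) w <- w - beta[j - 1] * V[, j - 1]
      w <- w - V[, seq_len(j), drop = FALSE] %*% crossprod(Conj(V[, seq_len(j), drop = FALSE]), w)
      b <- sqrt(sum(Mod(w)^2))
      if (b < 1e-13 || j == m || j == n) { k <- j; break }
      beta[j] <- b
      V[, j + 1] <- w / b
    }
    Tj <- .tridiag(alpha[seq_len(k)], beta[seq_len(k - 1)])
    ee <- eigen(Tj, symmetric = TRUE)
    lam <- ee$values[k]
    y <- ee$vectors[, k]
    v <- as.vector(V[, seq_len(k), drop = FALSE] %*% y)
    v <- v / sqrt(sum(Mod(v)^2))
    resid <- sqrt(sum(Mod(afun(v) - lam * v)^2))
    if (resid < tol * max(1, abs(lam)) || k == n) break
  }
  list(value = lam, vector = v)
}
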