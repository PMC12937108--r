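# Low-level tensor contractions for MPS/MPO algebra.  MPS site tensors are
# complex arrays (left bond x physical x right bond); MPO site tensors are
# complex arrays (left bond x physical-out x physical-in x right bond).
# Environments are rank-3 arrays (ket bond x MPO bond x bra bond).
# All contractions are phrased as matrix products (BLAS zgemm).

.m <- function(x, nr) { dim(x) <- c(nr, length(x) / nr); x }

# L' = contract environment L across one site (ket A, operator W, bra B)
contract_env_left <- function(L, A, W, B) {
  dl <- dim(L); da <- dim(A); dw <- dim(W); db <- dim(B)
  # T1[wl, lb, si, rk] = sum_lk L[lk, wl, lb] A[lk, si, rk]
  T1 <- crossprod(.m(L, dl[1]), .m(A, da[1]))
  dim(T1) <- c(dl[2], dl[3], da[2], da[3])
  # T2[so, wr, lb, rk] = sum_{wl, si} W[wl, so, si, wr] T1[wl, lb, si, rk]
  T1 <- aperm(T1, c(1, 3, 2, 4))
  Wm <- aperm(W, c(1, 3, 2, 4))
  T2 <- crossprod(.m(Wm, dw[1] * dw[3]), .m(T1, dw[1] * dw[3]))
  dim(T2) <- c(dw[2], dw[4], dl[3], da[3])
  # T3[rb, wr, rk] = sum_{lb, so} Conj(B)[lb, so, rb] T2[so, wr, lb, rk]
  T2 <- aperm(T2, c(3, 1, 2, 4))
  T3 <- crossprod(Conj(.m(B, db[1] * db[2])), .m(T2, db[1] * db[2]))
  dim(T3) <- c(db[3], dw[4], da[3])
  aperm(T3, c(3, 2, 1))
}

# R' = contract environment R across one site from the right
contract_env_right <- function(R, A, W, B) {
  dr <- dim(R); da <- dim(A); dw <- dim(W); db <- dim(B)
  # T1[lk, si, wr, rb] = sum_rk A[lk, si, rk] R[rk, wr, rb]
  T1 <- .m(A, da[1] * da[2]) %*% .m(R, dr[1])
  dim(T1) <- c(da[1], da[2], dr[2], dr[3])
  # T2[so, wl, lk, rb] = sum_{si, wr} W[wl, so, si, wr] T1[lk, si, wr, rb]
  T1 <- aperm(T1, c(2, 3, 1, 4))
  Wm <- aperm(W, c(3, 4, 2, 1))
  T2 <- crossprod(.m(Wm, dw[3] * dw[4]), .m(T1, dw[3] * dw[4]))
  dim(T2) <- c(dw[2], dw[1], da[1], dr[3])
  # T3[lb, wl, lk] = sum_{so, rb} Conj(B)[lb, so, rb] T2[so, wl, lk, rb]
  T2 <- aperm(T2, c(1, 4, 2, 3))
  Bm <- aperm(B, c(2, 3, 1))
  T3 <- crossprod(Conj(.m(Bm, db[2] * db[3])), .m(T2, db[2] * db[3]))
  dim(T3) <- c(db[1], dw[1], da[1])
  aperm(T3, c(3, 2, 1))
}

# one-site effective Hamiltonian applied to a center tensor A (l, s, r)
apply_heff1 <- function(L, W, R, A) {
  dl <- dim(L); dw <- dim(W); dr <- dim(R); da <- dim(A)
  T1 <- crossprod(.m(L, dl[1]), .m(A, da[1]))          # (wl*lb, si*rk)
  dim(T1) <- c(dl[2], dl[3], da[2], da[3])
  T1 <- aperm(T1, c(1, 3, 2, 4))                       # (wl, si, lb, rk)
  Wm <- aperm(W, c(1, 3, 2, 4))
  T2 <- crossprod(.m(Wm, dw[1] * dw[3]), .m(T1, dw[1] * dw[3]))
  dim(T2) <- c(dw[2], dw[4], dl[3], da[3])             # (so, wr, lb, rk)
  T2 <- aperm(T2, c(4, 2, 1, 3))                       # (rk, wr, so, lb)
  T3 <- crossprod(.m(R, dr[1] * dr[2]), .m(T2, dr[1] * dr[2]))
  dim(T3) <- c(dr[3], dw[2], dl[3])                    # (rb, so, lb)
  aperm(T3, c(3, 2, 1))
}

# two-site effective Hamiltonian applied to a bond tensor Th (l, s1, s2, r)
apply_heff2 <- function(L, W1, W2, R, Th) {
  dl <- dim(L); d1 <- dim(W1); d2 <- dim(W2); dr <- dim(R); dt <- dim(Th)
  T1 <- crossprod(.m(L, dl[1]), .m(Th, dt[1]))
  dim(T1) <- c(dl[2], dl[3], dt[2], dt[3], dt[4])      # (wl, lb, s1i, s2i, rk)
  T1 <- aperm(T1, c(1, 3, 2, 4, 5))                    # (wl, s1i, lb, s2i, rk)
  W1m <- aperm(W1, c(1, 3, 2, 4))
  T2 <- crossprod(.m(W1m, d1[1] * d1[3]), .m(T1, d1[1] * d1[3]))
  dim(T2) <- c(d1[2], d1[4], dl[3], dt[3], dt[4])      # (s1o, wm, lb, s2i, rk)
  T2 <- aperm(T2, c(2, 4, 1, 3, 5))                    # (wm, s2i, s1o, lb, rk)
  W2m <- aperm(W2, c(1, 3, 2, 4))
  T3 <- crossprod(.m(W2m, d2[1] * d2[3]), .m(T2, d2[1] * d2[3]))
  dim(T3) <- c(d2[2], d2[4], d1[2], dl[3], dt[4])      # (s2o, wr, s1o, lb, rk)
  T3 <- aperm(T3, c(5, 2, 1, 3, 4))                    # (rk, wr, s2o, s1o, lb)
  T4 <- crossprod(.m(R, dr[1] * dr[2]), .m(T3, dr[1] * dr[2]))
  dim(T4) <- c(dr[3], d2[2], d1[2], dl[3])             # (rb, s2o, s1o, lb)
  aperm(T4, c(4, 3, 2, 1))
}

# transfer-matrix step for expectations/overlaps: T (lk x lb) -> T' (rk x rb),
# with ket tensor A, bra tensor B (conjugated here) and an optional local
# operator O[so, si] inserted at this site
transfer_step <- function(T, A, B = A, op = NULL) {
  da <- dim(A); db <- dim(B)
  T1 <- crossprod(.m(A, da[1]), T)                     # (si*rk, lb)
  dim(T1) <- c(da[2], da[3], db[1])
  if (!is.null(op)) {
    T1 <- op %*% .m(T1, da[2])                         # (so, rk*lb)
    dim(T1) <- c(nrow(op), da[3], db[1])
  }
  T1 <- aperm(T1, c(3, 1, 2))                          # (lb, so, rk)
  T2 <- crossprod(Conj(.m(B, db[1] * db[2])), .m(T1, db[1] * db[2]))
  t(T2)                                                # (rk, rb)
}
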