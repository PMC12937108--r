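# Observables of the propagated vibronic wavepacket: Condon excitation,
# autocorrelation, diabatic electronic populations, and the absorption
# spectrum obtained as the half-line Fourier transform of C(t).

#' Condon initial wavepacket
#'
#' Places the vibrational ground-state wavepacket on the target electronic
#' surface: with the ground-state modal basis the vibrational part of the
#' initial excited wavepacket is the all-zeros occupation product state, so
#' the Condon state is the bond-dimension-1 MPS with electronic state
#' `gamma` occupied.  The constant transition dipole `mu0` only scales the
#' overall spectral intensity and is recorded, not applied to the
#' normalized state.
#'
#' @param lattice a `vib_lattice` (or `sq_hamiltonian`).
#' @param gamma target electronic state.
#' @param mu a [dipole_model()]; only `mu0` is used.
#' @param occ optional nonzero modal occupations of the ground wavepacket
#'   (zero-based; defaults to the true ground-state choice of all zeros).
#' @return a normalized `vibronic_mps` with attribute `mu0`.
#' @export
condon_initial_state <- function(lattice, gamma, mu = dipole_model(1), occ = NULL) {
  lat <- .lattice_of(lattice)
  if (gamma < 1 || gamma > lat$n_el) stop("target electronic state out of range")
  psi <- product_state(lat, gamma, occ)
  attr(psi, "mu0") <- mu$mu0
  psi
}

#' Diabatic electronic-state populations
#'
#' Expectation values of the electronic number operators
#' `N_gamma = a^dag_gamma a_gamma`, normalized by the state's norm; values
#' lie in `[0, 1]` and sum to 1 for a charge-1 state.
#'
#' @param psi a `vibronic_mps`.
#' @return numeric vector of length `n_el`.
#' @export
populations <- function(psi) {
  lat <- psi$lattice
  nops <- stats::setNames(lapply(seq_len(lat$n_el), function(g) .op_elec("n")),
                          as.character(seq_len(lat$n_el)))
  vals <- Re(mps_site_expectations(psi, nops))
  vals / mps_norm(psi)^2
}

#' Autocorrelation series of a propagation record
#'
#' @param record a `propagation_record` from [tdvp_propagate()] (or any data
#'   frame with `time_fs`, `re_C`, `im_C` columns).
#' @return list with `times_fs` and complex `C`.
#' @export
autocorrelation <- function(record) {
  list(times_fs = record$time_fs,
       C = complex(real = record$re_C, imaginary = record$im_C))
}

#' Absorption spectrum from an autocorrelation function
#'
#' Computes the half-line Fourier transform
#' `I(w) = sum_n w_n exp(i w t_n) C(t_n) dt` (trapezoid end weights) on a
#' uniform frequency grid and reports the complex value and its magnitude
#' `|I(w)|`.  No zero padding and no broadening are applied by default; both
#' exist as explicit options and their use is recorded in the metadata, as
#' is the 0-0 shift added to the frequency axis.
#'
#' @param record a `propagation_record`, or a list with `times_fs` and `C`.
#' @param shift 0-0 transition energy added to the frequency axis
#'   (in `unit`).
#' @param unit frequency axis unit: `"au"`, `"ev"` or `"cm-1"`.
#' @param omega optional explicit frequency grid (in `unit`, before shift);
#'   default: `n_pad + n` FFT-style frequencies `2 pi k / T`.
#' @param pad zero-pad the series to `pad` times its length (1 = none).
#' @param broadening optional Gaussian damping time `tau_fs`: multiplies
#'   `C(t)` by `exp(-(t/tau)^2)`.
#' @return object of class `vib_spectrum`: data frame with columns `omega`
#'   (shifted axis, in `unit`), `re_I`, `im_I`, `magnitude`; metadata in
#'   attributes.
#' @export
absorption_spectrum <- function(record, shift = 0, unit = c("au", "ev", "cm-1"),
                                omega = NULL, pad = 1L, broadening = NULL) {
  unit <- match.arg(unit)
  if (is.data.frame(record)) record <- autocorrelation(record)
  t_au <- fs_to_au(record$times_fs)
  C <- record$C
  n <- length(t_au)
  stopifnot(n >= 2)
  dt <- t_au[2] - t_au[1]
  if (max(abs(diff(t_au) - dt)) > 1e-9 * dt) stop("time grid is not uniform")
  if (!is.null(broadening)) C <- C * exp(-(record$times_fs / broadening)^2)
  if (pad > 1L) {
    C <- c(C, rep(0i, (pad - 1L) * n))
    t_au <- seq(0, by = dt, length.out = length(C))
    n <- length(C)
  }
  conv <- switch(unit, au = 1, ev = .HARTREE_EV, `cm-1` = .HARTREE_CM)
  if (is.null(omega)) {
    Ttot <- dt * (n - 1L)   # total propagation time; grid resolution 2*pi/T
    omega_au <- 2 * pi * seq(0, n - 1L) / Ttot
  } else {
    omega_au <- omega / conv
  }
  wts <- rep(1, n); wts[1] <- 0.5; wts[n] <- 0.5
  phase <- exp(1i * outer(omega_au, t_au))
  I <- as.vector(phase %*% (wts * C)) * dt
  out <- data.frame(omega = (omega_au + shift / conv) * conv,
                    re_I = Re(I), im_I = Im(I), magnitude = Mod(I))
  attr(out, "meta") <- list(unit = unit, shift = shift, dt_au = dt,
                            T_au = dt * (n - 1L), pad = pad,
                            broadening_fs = broadening)
  class(out) <- c("vib_spectrum", class(out))
  out
}

#' @export
print.vib_spectrum <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("<vib_spectrum> %d frequencies [%s], T = %.4g a.u., shift %.6g, pad %dx, %s\n",
              nrow(x), m$unit, m$T_au, m$shift, m$pad,
              if (is.null(m$broadening_fs)) "no broadening"
              else sprintf("Gaussian tau = %g fs", m$broadening_fs)))
  invisible(x)
}

#' Locate spectral peaks
#'
#' Local maxima of the magnitude above a relative floor, with quadratic
#' (three-point parabola) sub-grid refinement of position and height.
#'
#' @param spectrum a `vib_spectrum`.
#' @param floor minimum peak height relative to the global maximum.
#' @return data frame with columns `omega` and `height`, sorted by `omega`.
#' @export
find_peaks <- function(spectrum, floor = 0.01) {
  y <- spectrum$magnitude
  x <- spectrum$omega
  n <- length(y)
  thr <- floor * max(y)
  idx <- which(y[c(-1, -n)] > y[seq_len(n - 2)] &
               y[c(-1, -n)] >= y[seq(3, n)] &
               y[c(-1, -n)] > thr) + 1L
  if (!length(idx)) return(data.frame(omega = numeric(), height = numeric()))
  om <- hh <- numeric(length(idx))
  dx <- x[2] - x[1]
  for (j in seq_along(idx)) {
    i <- idx[j]
    a <- y[i - 1]; b <- y[i]; c <- y[i + 1]
    den <- a - 2 * b + c
    delta <- if (abs(den) > 0) 0.5 * (a - c) / den else 0
    delta <- max(-0.5, min(0.5, delta))
    om[j] <- x[i] + delta * dx
    hh[j] <- b - 0.25 * (a - c) * delta
  }
  data.frame(omega = om, height = hh)
}
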