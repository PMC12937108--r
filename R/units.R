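# Atomic units throughout (hbar = 1, mass-weighted normal coordinates).
# Conversion factors: CODATA values.

.HARTREE_CM <- 219474.6313632      # 1 hartree in cm^-1
.HARTREE_EV <- 27.211386245988     # 1 hartree in eV
.AU_TIME_FS <- 2.418884326509e-2   # 1 a.u. of time in fs

#' Unit conversions
#'
#' Helpers converting between the internal atomic units (hartree for energies
#' and frequencies, a.u. for time) and the spectroscopic units used at the
#' interface (wavenumbers, electronvolts, femtoseconds).
#'
#' @param x numeric value(s) to convert.
#' @return converted numeric value(s).
#' @name units
NULL

#' @rdname units
#' @export
cm_to_au <- function(x) x / .HARTREE_CM

#' @rdname units
#' @export
au_to_cm <- function(x) x * .HARTREE_CM

#' @rdname units
#' @export
ev_to_au <- function(x) x / .HARTREE_EV

#' @rdname units
#' @export
au_to_ev <- function(x) x * .HARTREE_EV

#' @rdname units
#' @export
fs_to_au <- function(x) x / .AU_TIME_FS

#' @rdname units
#' @export
au_to_fs <- function(x) x * .AU_TIME_FS
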