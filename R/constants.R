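#' Physical constants used throughout the package
#'
#' Exact SI values (2019 redefinition) plus the nuclear data for \eqn{^{23}}Na:
#' spin \eqn{I = 3/2} and electric quadrupole moment
#' \eqn{Q = 104 \times 10^{-31}\,\mathrm{m^2}}.
#'
#' Internal unit conventions: lengths in Angstrom, times in fs, charges in
#' units of the elementary charge e, temperatures in Kelvin. EFG tensors are
#' carried in e per cubic Angstrom and converted to SI (V m^-2) only inside
#' the rate formulas via `efg_to_si_factor`.
#'
#' @format A list with elements:
#' \describe{
#'   \item{k_B}{Boltzmann constant, J/K.}
#'   \item{hbar}{Reduced Planck constant, J s.}
#'   \item{e}{Elementary charge, C.}
#'   \item{eps0}{Vacuum permittivity, F/m.}
#'   \item{Q_23Na}{Quadrupole moment of 23Na, m^2.}
#'   \item{I_23Na}{Nuclear spin of 23Na.}
#'   \item{efg_to_si_factor}{Multiplier converting an EFG from e Angstrom^-3
#'     to V m^-2, equal to e / (4 pi eps0 1e-30).}
#' }
#' @export
#' @examples
#' physical_constants$Q_23Na
physical_constants <- local({
  e    <- 1.602176634e-19
  eps0 <- 8.8541878128e-12
  list(
    k_B  = 1.380649e-23,
    hbar = 1.054571817e-34,
    e    = e,
    eps0 = eps0,
    Q_23Na = 104e-31,
    I_23Na = 3 / 2,
    efg_to_si_factor = e / (4 * pi * eps0 * 1e-30)
  )
})

#' Convert EFG values between reduced and SI units
#'
#' The package stores EFGs in e Angstrom^-3; SI EFGs (V m^-2) are needed in
#' the quadrupolar coupling constant. The conversion factor is
#' e / (4 pi eps0) scaled by Angstrom^-3.
#'
#' @param v numeric EFG value(s).
#' @return converted value(s).
#' @export
efg_to_si <- function(v) v * physical_constants$efg_to_si_factor

#' @rdname efg_to_si
#' @export
efg_from_si <- function(v) v / physical_constants$efg_to_si_factor
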