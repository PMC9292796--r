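#' Physical constants used throughout the kinetics pipeline
#'
#' CODATA 2018 values. Energies at the thermodynamic layer are carried in
#' kcal mol^-1; diffusion arithmetic is done in SI and converted back to
#' M^-1 s^-1 at the end.
#'
#' @return A named list with elements
#'   \describe{
#'     \item{kB}{Boltzmann constant, J K^-1.}
#'     \item{h}{Planck constant, J s.}
#'     \item{N_A}{Avogadro number, mol^-1.}
#'     \item{R_kcal}{Gas constant, kcal mol^-1 K^-1.}
#'     \item{R_J}{Gas constant, J mol^-1 K^-1.}
#'     \item{atm_Pa}{Standard atmosphere, Pa.}
#'     \item{hc_over_kB}{hc/kB, cm K; converts a wavenumber to a temperature.}
#'   }
#' @examples
#' const <- physical_constants()
#' const$kB * 298.15 / const$h   # TST prefactor at 298.15 K, ~6.21e12 s^-1
#' @export
physical_constants <- function() {
  list(
    kB = 1.380649e-23,
    h = 6.62607015e-34,
    N_A = 6.02214076e23,
    R_kcal = 8.31446261815324 / 4184,
    R_J = 8.31446261815324,
    atm_Pa = 101325,
    hc_over_kB = 1.43877
  )
}

#' Thermal energy RT in kcal mol^-1
#'
#' @param temperature Temperature in K.
#' @return RT in kcal mol^-1 (0.5925 at 298.15 K).
#' @export
rt_kcal <- function(temperature = 298.15) {
  stopifnot(is.numeric(temperature), all(temperature > 0))
  physical_constants()$R_kcal * temperature
}

#' Ideal-gas molar volume at 1 atm
#'
#' V_M = RT/P, the volume of one mole of ideal gas, used by the
#' 1 atm -> 1 M standard-state conversion.
#'
#' @param temperature Temperature in K.
#' @param pressure Pressure in Pa (default 1 atm).
#' @return Molar volume in L mol^-1 (24.465 at 298.15 K, 1 atm).
#' @export
molar_volume <- function(temperature = 298.15, pressure = 101325) {
  stopifnot(all(temperature > 0), all(pressure > 0))
  const <- physical_constants()
  const$R_J * temperature / pressure * 1000
}
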