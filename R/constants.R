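# Physical constants and unit conversions used throughout.
# Internal unit conventions: lengths nm, energies kcal/mol, spring constants
# accepted in kJ mol^-1 nm^-2 (the MD convention) and converted on entry.

.kB_kJ <- 0.008314462618          # Boltzmann x Avogadro, kJ mol^-1 K^-1
.KJ_PER_KCAL <- 4.184
# 1 pN nm = 1e-21 J; per mole: x N_A, -> kcal/mol
.PN_NM_TO_KCAL <- 1e-21 * 6.02214076e23 / 1000 / .KJ_PER_KCAL

#' Thermal energy kT in kcal/mol
#'
#' @param temperature Temperature in Kelvin. Default 320 K, the thermostat
#'   temperature of the simulations this pipeline analyses (kT = 0.6359
#'   kcal/mol).
#' @return kT in kcal/mol.
#' @export
#' @examples
#' kT_kcal(320)
kT_kcal <- function(temperature = 320) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  .kB_kJ * temperature / .KJ_PER_KCAL
}

#' Convert a spring constant from kJ mol^-1 nm^-2 to kcal mol^-1 nm^-2
#' @param k Spring constant in kJ mol^-1 nm^-2.
#' @return Spring constant in kcal mol^-1 nm^-2.
#' @export
spring_kcal <- function(k) k / .KJ_PER_KCAL

#' Convert line tension x length to a molar free energy
#'
#' 1 pN nm = 1e-21 J = 0.14393 kcal/mol.
#'
#' @param pn_nm Energy in pN nm.
#' @return Energy in kcal/mol.
#' @export
pn_nm_to_kcal <- function(pn_nm) pn_nm * .PN_NM_TO_KCAL
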