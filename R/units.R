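#' Physical constants and unit conversions
#'
#' All internal energies are kJ mol^-1, lengths nm, temperatures K.
#' Free-energy profiles are reported in kcal mol^-1, the unit in which
#' association free energies are conventionally quoted for
#' carrier-membrane binding.
#'
#' @name nanomem-units
#' @keywords internal
NULL

## Boltzmann constant times Avogadro, kJ mol^-1 K^-1 (CODATA)
KB_KJ <- 0.008314462618

## thermal energy at temperature T, kJ mol^-1
kT_kJ <- function(temperature) KB_KJ * temperature

#' Convert kJ mol^-1 to kcal mol^-1
#' @param x energy in kJ mol^-1
#' @return energy in kcal mol^-1 (thermochemical calorie, 4.184 J)
#' @export
kj_to_kcal <- function(x) x / 4.184

#' Convert kcal mol^-1 to kJ mol^-1
#' @param x energy in kcal mol^-1
#' @return energy in kJ mol^-1
#' @export
kcal_to_kj <- function(x) x * 4.184

## default thermostat temperature, K
DEFAULT_TEMPERATURE <- 310
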