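#' Allometric individual metabolic rate
#'
#' Metabolic loss of an average individual as a function of body mass M (mg)
#' and system temperature T (Kelvin):
#' X = exp(ln x0 + a ln M - E / (k T)), in J/h, with k the Boltzmann constant
#' (8.617e-5 eV/K) and E an activation energy in eV. Coefficients are
#' group-specific and supplied per taxon in the trait table.
#'
#' @param mass body mass in mg (vectorized).
#' @param ln_x0 regression intercept on the ln scale.
#' @param a mass-scaling exponent (typically ~0.7 for invertebrates).
#' @param E activation energy in eV.
#' @param temperature system temperature in Kelvin. The default corresponds to
#'   a 15 degC controlled climate.
#' @return Metabolic rate in J/h per individual.
#' @export
#' @examples
#' individual_metabolic_rate(exp(1), ln_x0 = 0, a = 1, E = 0) # = e
individual_metabolic_rate <- function(mass, ln_x0, a, E,
                                      temperature = 288.15) {
  if (any(mass <= 0)) abort("body mass must be positive")
  if (any(temperature <= 0)) abort("temperature must be positive (Kelvin)")
  exp(ln_x0 + a * log(mass) - E / (.k_boltzmann * temperature))
}

#' Population-level metabolic loss
#'
#' The average individual's metabolic rate at the population's mean body mass,
#' multiplied by the number of individuals.
#'
#' @inheritParams individual_metabolic_rate
#' @param density individuals per mesocosm (vectorized).
#' @param mean_body_mass mean individual body mass in mg.
#' @return Population metabolic loss in J/h per mesocosm.
#' @export
population_metabolic_loss <- function(density, mean_body_mass, ln_x0, a, E,
                                      temperature = 288.15) {
  if (any(density < 0)) abort("density must be nonnegative")
  mass <- ifelse(density == 0, 1, mean_body_mass) # unused when density is 0
  density * individual_metabolic_rate(mass, ln_x0, a, E, temperature)
}
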