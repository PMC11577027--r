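#' Describe a soil sampling core
#'
#' @param diameter core diameter in cm.
#' @param n_cores number of cores pooled into one sample.
#' @param depth sampling depth in cm (10 cm in the reference protocol).
#' @param fresh_soil_mass grams of fresh soil extracted (nematode sampling).
#' @param dry_fraction grams of dry soil per gram of fresh soil (nematode
#'   sampling).
#' @param dry_soil_density dry soil bulk density in g per cm^3 (nematode
#'   sampling).
#' @return A `core_spec` list.
#' @export
core_spec <- function(diameter, n_cores = 1L, depth = 10,
                      fresh_soil_mass = NA_real_, dry_fraction = NA_real_,
                      dry_soil_density = NA_real_) {
  if (diameter <= 0) abort("core diameter must be positive")
  if (n_cores < 1) abort("n_cores must be at least 1")
  structure(list(diameter = diameter, n_cores = as.integer(n_cores),
                 depth = depth, fresh_soil_mass = fresh_soil_mass,
                 dry_fraction = dry_fraction,
                 dry_soil_density = dry_soil_density),
            class = "core_spec")
}

#' Default sampler set: 15 cm macrofauna, 5 cm mesofauna, 3 x 2 cm nematode
#' cores, all to 10 cm depth
#'
#' Nematode soil-moisture fields default to `NA` and are supplied per
#' mesocosm.
#'
#' @return Named list of [core_spec()] objects keyed by fauna class.
#' @export
default_cores <- function() {
  list(macrofauna = core_spec(15),
       mesofauna = core_spec(5),
       nematode = core_spec(2, n_cores = 3))
}

#' Scale a core count to individuals per mesocosm by surface area
#'
#' Density per mesocosm = count x (mesocosm surface) / (total core surface),
#' total core surface being `n_cores` x pi (d/2)^2.
#'
#' @param count individuals found in the (pooled) core sample.
#' @param core a [core_spec()].
#' @param mesocosm_diameter mesocosm diameter in cm (50 for the reference
#'   lysimeters).
#' @return Individuals per mesocosm.
#' @export
#' @examples
#' scale_core_abundance(1, core_spec(15)) # (50/15)^2 = 11.11
scale_core_abundance <- function(count, core, mesocosm_diameter = 50) {
  if (any(count < 0)) abort("count must be nonnegative")
  core_area <- core$n_cores * pi * (core$diameter / 2)^2
  if (core_area <= 0) abort("core area must be positive")
  meso_area <- pi * (mesocosm_diameter / 2)^2
  if (meso_area <= 0) abort("mesocosm area must be positive")
  count * meso_area / core_area
}

#' Scale a nematode count to individuals per mesocosm via dry-soil mass
#'
#' Nematodes are extracted from a known fresh-soil mass, so the count is first
#' converted to individuals per gram of dry soil (dividing by
#' `fresh_soil_mass` x `dry_fraction`), then to individuals per cm^3 using the
#' dry soil bulk density, and finally multiplied by the sampled soil volume
#' scaled to the whole mesocosm surface (mesocosm area x core depth).
#'
#' @inheritParams scale_core_abundance
#' @return Individuals per mesocosm.
#' @export
scale_nematode_abundance <- function(count, core, mesocosm_diameter = 50) {
  if (any(count < 0)) abort("count must be nonnegative")
  if (is.na(core$fresh_soil_mass) || core$fresh_soil_mass <= 0) {
    abort("fresh_soil_mass must be positive")
  }
  if (is.na(core$dry_fraction) || core$dry_fraction <= 0 ||
      core$dry_fraction > 1) {
    abort("dry_fraction must lie in (0, 1]")
  }
  if (is.na(core$dry_soil_density) || core$dry_soil_density <= 0) {
    abort("dry_soil_density must be positive")
  }
  per_g_dry <- count / (core$fresh_soil_mass * core$dry_fraction)
  per_cm3 <- per_g_dry * core$dry_soil_density
  volume <- pi * (mesocosm_diameter / 2)^2 * core$depth
  per_cm3 * volume
}

#' Apportion a total density over taxa by identified composition
#'
#' When only a subsample is identified to taxon (e.g. up to 100 nematodes per
#' mesocosm), the total density is split proportionally to the identified
#' counts; the apportioned densities sum to the total exactly.
#'
#' @param total_density total individuals per mesocosm.
#' @param identified_counts named numeric vector of identified individuals per
#'   taxon.
#' @return Named numeric vector of per-taxon densities.
#' @export
apportion_to_taxa <- function(total_density, identified_counts) {
  if (any(identified_counts < 0)) abort("identified counts must be nonnegative")
  s <- sum(identified_counts)
  if (s <= 0) abort("identified counts are all zero")
  total_density * identified_counts / s
}
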