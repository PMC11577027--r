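#' Build per-mesocosm communities from raw sample records
#'
#' Turns raw faunal sample records (counts and individual measurements per
#' taxon per mesocosm) into populations: density (individuals per mesocosm),
#' mean individual body mass (mg) and biomass (mg per mesocosm).
#'
#' Macro- and mesofauna counts are scaled by the ratio of mesocosm to core
#' surface area ([scale_core_abundance()]). Nematode records hold identified
#' counts; the total extracted count per mesocosm (in `nematode_soil`) is
#' scaled through fresh/dry soil mass and bulk density
#' ([scale_nematode_abundance()]) and then apportioned over nematode taxa by
#' identified composition ([apportion_to_taxa()]).
#'
#' Body masses come from per-individual allometric regressions
#' ([estimate_body_mass()]). A taxon with no measurements in a mesocosm falls
#' back to its mean estimated mass across the other mesocosms, and failing
#' that to the trait table's `fixed_body_mass`.
#'
#' @param samples data frame with columns `mesocosm_id`, `taxon_id`, `count`
#'   and optionally `lengths` and `widths` (each either a list-column of
#'   numeric vectors or a `";"`-separated character column, measurements in
#'   mm). For nematode taxa `count` is the identified count.
#' @param traits a [trait_table()] covering every sampled taxon.
#' @param cores named list of [core_spec()] per fauna class (default:
#'   [default_cores()]).
#' @param nematode_soil data frame with one row per mesocosm containing
#'   nematode taxa: `mesocosm_id`, `total_count` (individuals extracted),
#'   `fresh_soil_mass` (g), `dry_fraction` (g dry / g fresh),
#'   `dry_soil_density` (g per cm^3). May be `NULL` when no nematodes were
#'   sampled.
#' @param mesocosm_diameter mesocosm diameter in cm.
#' @return Tibble of populations: `mesocosm_id`, `taxon_id`, `fauna_class`,
#'   `density`, `mean_body_mass`, `biomass`.
#' @export
build_communities <- function(samples, traits, cores = default_cores(),
                              nematode_soil = NULL, mesocosm_diameter = 50) {
  stopifnot(inherits(traits, "trait_table"))
  samples <- tibble::as_tibble(samples)
  req <- c("mesocosm_id", "taxon_id", "count")
  miss <- setdiff(req, names(samples))
  if (length(miss) > 0) {
    abort(paste0("sample records missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  unknown <- validate_against_samples(traits, samples$taxon_id)
  if (length(unknown) > 0) {
    abort(paste0("sampled taxa absent from trait table: ",
                 paste(unknown, collapse = ", ")))
  }
  if (any(samples$count < 0)) abort("negative sample count")

  tx <- traits$taxa
  samples$lengths <- .parse_measurements(samples$lengths %||%
                                           rep(NA_character_, nrow(samples)))
  samples$widths <- .parse_measurements(samples$widths %||%
                                          rep(NA_character_, nrow(samples)))
  samples <- dplyr::left_join(
    samples,
    tx[c("taxon_id", "fauna_class", "lw_form", "lw_a", "lw_b",
         "fixed_body_mass")],
    by = "taxon_id")

  # per-record mass; NA when no measurements so the fallback chain can apply
  raw_mass <- purrr::pmap_dbl(
    samples[c("lengths", "widths", "lw_form", "lw_a", "lw_b")],
    function(lengths, widths, lw_form, lw_a, lw_b) {
      lengths <- lengths[!is.na(lengths)]
      if (length(lengths) == 0 || is.na(lw_form)) return(NA_real_)
      estimate_body_mass(lengths, widths, form = lw_form, a = lw_a, b = lw_b)
    })
  samples$mean_body_mass <- raw_mass
  taxon_means <- tapply(raw_mass, samples$taxon_id, mean, na.rm = TRUE)
  need <- which(is.na(samples$mean_body_mass))
  for (i in need) {
    tm <- taxon_means[[samples$taxon_id[i]]]
    samples$mean_body_mass[i] <- if (!is.na(tm)) {
      tm
    } else if (!is.na(samples$fixed_body_mass[i])) {
      samples$fixed_body_mass[i]
    } else if (samples$count[i] == 0) {
      0 # absent population: mass is moot, biomass stays 0
    } else {
      abort(paste0("no body-mass information for taxon ",
                   samples$taxon_id[i]))
    }
  }

  # densities
  is_nema <- samples$fauna_class == "nematode"
  dens <- rep(NA_real_, nrow(samples))
  for (cls in c("macrofauna", "mesofauna")) {
    idx <- samples$fauna_class == cls
    if (!any(idx)) next
    if (is.null(cores[[cls]])) abort(paste0("no core_spec for ", cls))
    dens[idx] <- scale_core_abundance(samples$count[idx], cores[[cls]],
                                      mesocosm_diameter)
  }
  if (any(is_nema)) {
    if (is.null(nematode_soil)) {
      abort("nematode taxa present but nematode_soil not supplied")
    }
    ns <- tibble::as_tibble(nematode_soil)
    base_core <- cores$nematode %||% abort("no core_spec for nematode")
    for (m in unique(samples$mesocosm_id[is_nema])) {
      row <- ns[ns$mesocosm_id == m, ]
      if (nrow(row) != 1) {
        abort(paste0("nematode_soil must have exactly one row for mesocosm ",
                     m))
      }
      core <- base_core
      core$fresh_soil_mass <- row$fresh_soil_mass
      core$dry_fraction <- row$dry_fraction
      core$dry_soil_density <- row$dry_soil_density
      total_density <- scale_nematode_abundance(row$total_count, core,
                                                mesocosm_diameter)
      idx <- which(is_nema & samples$mesocosm_id == m)
      dens[idx] <- apportion_to_taxa(
        total_density, setNames(samples$count[idx], samples$taxon_id[idx]))
    }
  }
  samples$density <- dens

  out <- samples |>
    dplyr::group_by(.data$mesocosm_id, .data$taxon_id, .data$fauna_class) |>
    dplyr::summarise(
      density = sum(.data$density),
      mean_body_mass = stats::weighted.mean(
        .data$mean_body_mass, .data$density + (sum(.data$density) == 0)),
      .groups = "drop") |>
    dplyr::mutate(biomass = .data$density * .data$mean_body_mass) |>
    dplyr::arrange(.data$mesocosm_id, .data$taxon_id)
  out
}

.parse_measurements <- function(x) {
  if (is.list(x)) {
    return(purrr::map(x, function(v) as.numeric(v[!is.na(v)])))
  }
  purrr::map(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) return(numeric())
    as.numeric(strsplit(s, ";", fixed = TRUE)[[1]])
  })
}

#' Community biomass, weighted mean body mass and diversity
#'
#' Per-mesocosm summary metrics of a populations table:
#' \describe{
#'   \item{biomass}{total standing fauna biomass, mg per mesocosm}
#'   \item{cwm_body_mass}{community-weighted mean body mass: the
#'     abundance-weighted mean of ln(mass), back-transformed — appropriate for
#'     right-skewed body-mass distributions}
#'   \item{diversity}{exponent of Shannon entropy of relative biomass: an
#'     effective number of taxa between 1 and the taxon richness}
#' }
#'
#' @param populations tibble as returned by [build_communities()] (columns
#'   `mesocosm_id`, `density`, `mean_body_mass`, `biomass`).
#' @return Tibble with one row per mesocosm: `mesocosm_id`, `n_taxa`,
#'   `biomass`, `cwm_body_mass`, `diversity`.
#' @export
community_metrics <- function(populations) {
  tibble::as_tibble(populations) |>
    dplyr::group_by(.data$mesocosm_id) |>
    dplyr::summarise(
      n_taxa = sum(.data$biomass > 0),
      biomass = community_biomass(.data$density, .data$mean_body_mass),
      cwm_body_mass = cwm_body_mass(.data$density, .data$mean_body_mass),
      diversity = shannon_exponent_diversity(.data$density *
                                               .data$mean_body_mass),
      .groups = "drop")
}

#' @rdname community_metrics
#' @param density individuals per mesocosm.
#' @param mean_body_mass mg per individual.
#' @return `community_biomass()`: total biomass in mg;
#' @export
community_biomass <- function(density, mean_body_mass) {
  sum(density * mean_body_mass)
}

#' @rdname community_metrics
#' @return `cwm_body_mass()`: exp of the density-weighted mean log mass (mg);
#' @export
cwm_body_mass <- function(density, mean_body_mass) {
  keep <- density > 0
  if (!any(keep)) abort("total density is zero")
  exp(sum(density[keep] * log(mean_body_mass[keep])) / sum(density[keep]))
}

#' @rdname community_metrics
#' @param biomass per-taxon biomasses (mg).
#' @return `shannon_exponent_diversity()`: effective number of taxa.
#' @export
shannon_exponent_diversity <- function(biomass) {
  keep <- biomass > 0
  if (!any(keep)) abort("total biomass is zero")
  p <- biomass[keep] / sum(biomass[keep])
  exp(-sum(p * log(p)))
}
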