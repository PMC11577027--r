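#' Blocked, nested mesocosm experiment design
#'
#' The reference layout: 24 EcoUnits (controlled-environment chambers)
#' arranged in 6 spatial blocks, each EcoUnit housing 4 mesocosms that cross
#' soil history with plant history, and one plant-richness level per EcoUnit.
#'
#' @param n_blocks number of blocks.
#' @param ecounits_per_block EcoUnits per block.
#' @param richness_levels plant richness levels cycled over the EcoUnits of
#'   each block.
#' @param seed optional seed; when given, richness levels are permuted within
#'   blocks (deterministic given the seed), otherwise assigned in order.
#' @return Tibble with one row per mesocosm: `block`, `ecounit`,
#'   `mesocosm_id`, `soil_history`, `plant_history`, `history` (factor with
#'   levels `none`, `plant`, `soil`, `soil_plant`), `plant_richness`.
#' @export
#' @examples
#' nrow(experiment_design()) # 96
experiment_design <- function(n_blocks = 6, ecounits_per_block = 4,
                              richness_levels = c(1, 2, 3, 6), seed = NULL) {
  n_eu <- n_blocks * ecounits_per_block
  rich_per_block <- rep_len(richness_levels, ecounits_per_block)
  richness <- unlist(lapply(seq_len(n_blocks), function(b) {
    if (is.null(seed)) rich_per_block else {
      set.seed(seed + b)
      sample(rich_per_block)
    }
  }))
  eu <- tibble::tibble(
    block = sprintf("B%d", rep(seq_len(n_blocks), each = ecounits_per_block)),
    ecounit = sprintf("E%02d", seq_len(n_eu)),
    plant_richness = richness)
  cells <- tibble::tibble(
    soil_history = c(FALSE, FALSE, TRUE, TRUE),
    plant_history = c(FALSE, TRUE, FALSE, TRUE))
  out <- tidyr::crossing(eu, cells) |>
    dplyr::arrange(.data$ecounit, .data$soil_history, .data$plant_history) |>
    dplyr::mutate(
      history = factor(
        dplyr::case_when(
          .data$soil_history & .data$plant_history ~ "soil_plant",
          .data$soil_history ~ "soil",
          .data$plant_history ~ "plant",
          TRUE ~ "none"),
        levels = c("none", "plant", "soil", "soil_plant")),
      mesocosm_id = sprintf("M%03d", dplyr::row_number())) |>
    dplyr::relocate("block", "ecounit", "mesocosm_id")
  out
}

#' Synthetic soil-fauna taxon pool
#'
#' A ~30-taxon trait table spanning nematodes (fixed reference body masses),
#' mesofauna and macrofauna (length–mass regressions), with realistic body
#' masses (1e-4 to 1e2 mg), trophic-group diet fractions, agility/defense
#' values and vertical strata. Besides the standard trait columns, the taxa
#' carry generator columns `base_mass` (characteristic individual mass, mg),
#' `base_density` (expected individuals per mesocosm, scaled roughly as
#' mass^-3/4 within fauna classes) and `base_width_ratio` (width:length, for
#' length–width regressions).
#'
#' @param seed seed controlling the (reproducible) jitter of masses and
#'   densities around class-typical values.
#' @return A [trait_table()] whose `taxa` tibble carries the extra generator
#'   columns.
#' @export
synthetic_traits <- function(seed = 1) {
  set.seed(seed)
  # group, n, diet fractions (animal/plant/microbe/detritus), agility,
  # defended, stratum, mass range (mg)
  groups <- tibble::tribble(
    ~group, ~n, ~fauna_class, ~fa, ~fp, ~fm, ~fd, ~agility, ~defended,
    ~stratum, ~mass_lo, ~mass_hi,
    "bact_nematode", 4, "nematode", 0, 0, 1, 0, 0.2, FALSE, "euedaphic",
    1e-4, 1e-3,
    "fung_nematode", 2, "nematode", 0, 0, 1, 0, 0.2, FALSE, "euedaphic",
    2e-4, 2e-3,
    "herb_nematode", 2, "nematode", 0, 1, 0, 0, 0.2, FALSE, "euedaphic",
    5e-4, 5e-3,
    "omni_nematode", 2, "nematode", 0.5, 0, 0.5, 0, 0.3, FALSE, "euedaphic",
    1e-3, 1e-2,
    "pred_nematode", 2, "nematode", 1, 0, 0, 0, 0.3, FALSE, "euedaphic",
    2e-3, 1e-2,
    "oribatid", 3, "mesofauna", 0, 0, 0.4, 0.6, 0.2, TRUE, "hemiedaphic",
    2e-3, 2e-2,
    "collembola", 3, "mesofauna", 0, 0.1, 0.5, 0.4, 0.8, FALSE, "hemiedaphic",
    1e-3, 5e-2,
    "pred_mite", 2, "mesofauna", 1, 0, 0, 0, 0.7, FALSE, "hemiedaphic",
    5e-3, 5e-2,
    "enchytraeid", 2, "mesofauna", 0, 0, 0.3, 0.7, 0.3, FALSE, "euedaphic",
    1e-2, 1e-1,
    "earthworm", 2, "macrofauna", 0, 0, 0.1, 0.9, 0.2, FALSE, "euedaphic",
    2e1, 1e2,
    "chilopod", 2, "macrofauna", 1, 0, 0, 0, 0.6, FALSE, "epigeic",
    1e0, 2e1,
    "spider", 1, "macrofauna", 1, 0, 0, 0, 0.8, FALSE, "epigeic",
    1e0, 1e1,
    "diplopod", 1, "macrofauna", 0, 0, 0.1, 0.9, 0.2, TRUE, "epigeic",
    1e1, 1e2,
    "isopod", 1, "macrofauna", 0, 0.1, 0.1, 0.8, 0.3, TRUE, "epigeic",
    5e0, 5e1,
    "herb_larva", 1, "macrofauna", 0, 0.8, 0, 0.2, 0.4, FALSE, "hemiedaphic",
    1e0, 2e1)

  rows <- purrr::pmap(groups, function(group, n, fauna_class, fa, fp, fm, fd,
                                       agility, defended, stratum, mass_lo,
                                       mass_hi) {
    mass <- exp(seq(log(mass_lo), log(mass_hi), length.out = n + 2)[-c(1, n + 2)])
    mass <- mass * exp(rnorm(n, 0, 0.1))
    tibble::tibble(
      taxon_id = sprintf("%s_%d", group, seq_len(n)),
      fauna_class = fauna_class,
      frac_animal = fa, frac_plant = fp, frac_microbe = fm, frac_detritus = fd,
      agility = agility, defended = defended, stratum = stratum,
      base_mass = mass)
  })
  taxa <- dplyr::bind_rows(rows)

  # published invertebrate-level metabolic regression (J/h, mg, eV)
  taxa$metab_ln_x0 <- 23.055
  taxa$metab_a <- 0.695
  taxa$metab_E <- 0.686

  is_nema <- taxa$fauna_class == "nematode"
  is_macro <- taxa$fauna_class == "macrofauna"
  taxa$fixed_body_mass <- ifelse(is_nema, taxa$base_mass, NA_real_)
  taxa$lw_form <- dplyr::case_when(is_nema ~ NA_character_,
                                   is_macro ~ "length_width",
                                   TRUE ~ "power")
  # power: M = a L^2.5; length_width: M = a (L W^2)^0.9, W = ratio * L
  taxa$lw_b <- ifelse(is_macro, 0.9, 2.5)
  taxa$base_width_ratio <- ifelse(is_macro, 0.2, NA_real_)
  taxa$base_length <- NA_real_
  meso <- taxa$fauna_class == "mesofauna"
  taxa$lw_a <- NA_real_
  # pick lw_a so the class-typical length of each taxon is plausible (mm)
  taxa$base_length[meso] <- (taxa$base_mass[meso] / 0.04)^(1 / 2.5)
  taxa$lw_a[meso] <- 0.04
  lv <- taxa$base_mass[is_macro]
  taxa$base_length[is_macro] <- (lv / (2 * 0.2^2 * 0.9))^(1 / 2.7)
  taxa$lw_a[is_macro] <- taxa$base_mass[is_macro] /
    (taxa$base_length[is_macro] *
       (taxa$base_width_ratio[is_macro] * taxa$base_length[is_macro])^2)^
      taxa$lw_b[is_macro]
  taxa$lw_form[is_nema] <- NA_character_
  taxa$lw_a[is_nema] <- NA_real_
  taxa$lw_b[is_nema] <- NA_real_

  # abundance: class totals per mesocosm split ~ mass^-0.75 within class
  class_total <- c(nematode = 2e5, mesofauna = 8e3, macrofauna = 250)
  taxa <- taxa |>
    dplyr::group_by(.data$fauna_class) |>
    dplyr::mutate(base_density = {
      w <- .data$base_mass^-0.75 * exp(rnorm(dplyr::n(), 0, 0.3))
      class_total[[unique(.data$fauna_class)]] * w / sum(w)
    }) |>
    dplyr::ungroup()

  trait_table(taxa)
}

#' Treatment-effect configuration of the synthetic generator
#'
#' Soil history acts as a compositional shift: per-taxon expected abundances
#' are tilted toward small-bodied taxa (multiplier proportional to
#' mass^-gamma) with gamma and an overall scale solved so that, in
#' expectation, community biomass is multiplied by
#' `soil_biomass_multiplier` and CWM body mass by `soil_cwm_multiplier`.
#' Within-taxon body masses are never shifted by treatment — mirroring
#' assembly acting through composition rather than individual growth.
#'
#' @param soil_biomass_multiplier expected biomass ratio, soil history vs
#'   none (> 0; default exp(0.41)).
#' @param soil_cwm_multiplier expected CWM body-mass ratio (> 0; default
#'   exp(-0.64)).
#' @param plant_multiplier abundance multiplier of plant history (default 1 =
#'   no effect).
#' @param richness_slope effect of standardized log plant richness on log
#'   abundance (default 0).
#' @param abundance_cv lognormal coefficient of variation of per-population
#'   abundance noise.
#' @param mass_cv lognormal cv of per-population mean body-mass noise.
#' @param sd_block,sd_ecounit standard deviations of block and
#'   EcoUnit-in-block random intercepts on the log-abundance scale.
#' @return An `effect_config` list.
#' @export
effect_config <- function(soil_biomass_multiplier = exp(0.41),
                          soil_cwm_multiplier = exp(-0.64),
                          plant_multiplier = 1, richness_slope = 0,
                          abundance_cv = 0.3, mass_cv = 0.15,
                          sd_block = 0.15, sd_ecounit = 0.1) {
  stopifnot(soil_biomass_multiplier > 0, soil_cwm_multiplier > 0,
            plant_multiplier > 0, abundance_cv >= 0, mass_cv >= 0,
            sd_block >= 0, sd_ecounit >= 0)
  structure(list(soil_biomass_multiplier = soil_biomass_multiplier,
                 soil_cwm_multiplier = soil_cwm_multiplier,
                 plant_multiplier = plant_multiplier,
                 richness_slope = richness_slope,
                 abundance_cv = abundance_cv, mass_cv = mass_cv,
                 sd_block = sd_block, sd_ecounit = sd_ecounit),
            class = "effect_config")
}

# Per-taxon soil-history abundance multipliers m_i = C * M_i^-gamma solved so
# that expected biomass and CWM body mass hit the configured ratios.
.soil_multipliers <- function(base_density, base_mass, effects) {
  lM <- log(base_mass)
  N <- base_density
  target_cwm <- log(effects$soil_cwm_multiplier)
  cwm0 <- sum(N * lM) / sum(N)
  gamma <- if (abs(target_cwm) < 1e-12) 0 else {
    shift <- function(g) {
      w <- N * exp(-g * lM)
      sum(w * lM) / sum(w) - cwm0 - target_cwm
    }
    uniroot(shift, c(-5, 5), extendInt = "yes", tol = 1e-12)$root
  }
  m <- base_mass^-gamma
  C <- effects$soil_biomass_multiplier * sum(N * base_mass) /
    sum(N * m * base_mass)
  C * m
}

#' Generate synthetic per-mesocosm communities
#'
#' Draws populations for every mesocosm of a design: expected log abundance =
#' baseline + block intercept + EcoUnit intercept + treatment terms +
#' lognormal noise; per-mesocosm mean body masses are the taxon's
#' characteristic mass times mean-one lognormal noise (identical in
#' distribution across treatments).
#'
#' @param design an [experiment_design()] tibble.
#' @param traits a [synthetic_traits()] trait table (needs the generator
#'   columns).
#' @param effects an [effect_config()].
#' @param seed RNG seed; communities are reproducible given the seed.
#' @return Populations tibble in [build_communities()] format.
#' @export
synthetic_communities <- function(design, traits = synthetic_traits(),
                                  effects = effect_config(), seed = 1) {
  tx <- traits$taxa
  if (!all(c("base_mass", "base_density") %in% names(tx))) {
    abort("traits must carry generator columns base_mass and base_density")
  }
  set.seed(seed)
  n_tx <- nrow(tx)
  meso <- dplyr::distinct(design, .data$block, .data$ecounit,
                          .data$mesocosm_id, .data$soil_history,
                          .data$plant_history, .data$plant_richness)
  n_m <- nrow(meso)

  m_soil <- .soil_multipliers(tx$base_density, tx$base_mass, effects)
  blocks <- unique(meso$block)
  eus <- unique(meso$ecounit)
  b_eff <- setNames(rnorm(length(blocks), 0, effects$sd_block), blocks)
  e_eff <- setNames(rnorm(length(eus), 0, effects$sd_ecounit), eus)
  z_rich <- as.vector(scale(log(meso$plant_richness)))
  if (any(is.na(z_rich))) z_rich <- rep(0, n_m) # single richness level

  sd_a <- sqrt(log(1 + effects$abundance_cv^2))
  sd_m <- sqrt(log(1 + effects$mass_cv^2))

  # n_m x n_tx matrices of expected log density and realized values
  log_mu <- outer(rep(1, n_m), log(tx$base_density)) +
    b_eff[meso$block] + e_eff[meso$ecounit] +
    outer(meso$soil_history, log(m_soil)) +
    meso$plant_history * log(effects$plant_multiplier) +
    effects$richness_slope * z_rich
  dens <- exp(log_mu + matrix(rnorm(n_m * n_tx, -sd_a^2 / 2, sd_a), n_m))
  mass <- outer(rep(1, n_m), tx$base_mass) *
    exp(matrix(rnorm(n_m * n_tx, -sd_m^2 / 2, sd_m), n_m))

  tibble::tibble(
    mesocosm_id = rep(meso$mesocosm_id, each = n_tx),
    taxon_id = rep(tx$taxon_id, n_m),
    fauna_class = rep(tx$fauna_class, n_m),
    density = as.vector(t(dens)),
    mean_body_mass = as.vector(t(mass))) |>
    dplyr::mutate(biomass = .data$density * .data$mean_body_mass)
}

#' Render synthetic communities as raw sample records
#'
#' Inverts the community builder: per-mesocosm densities become expected core
#' counts through the sampler geometry (Poisson-distributed by default);
#' individual body lengths (and widths for macrofauna) are drawn so that the
#' length–mass regressions recover the population's mean mass; nematode taxa
#' are emitted as identified counts with per-mesocosm soil-moisture data.
#'
#' @param communities populations tibble from [synthetic_communities()].
#' @param traits the [synthetic_traits()] table used to generate them.
#' @param seed RNG seed.
#' @param cores sampler set (default [default_cores()]).
#' @param count_noise `"poisson"` for integer Poisson counts, `"none"` for
#'   exact (fractional) expected counts.
#' @param mesocosm_diameter mesocosm diameter in cm.
#' @param max_measured maximum measured individuals per taxon per mesocosm.
#' @param max_identified maximum nematodes identified per mesocosm.
#' @return List with `samples` and `nematode_soil` tibbles, directly
#'   consumable by [build_communities()].
#' @export
generate_samples <- function(communities, traits, seed = 1,
                             cores = default_cores(),
                             count_noise = c("poisson", "none"),
                             mesocosm_diameter = 50, max_measured = 10,
                             max_identified = 100) {
  count_noise <- match.arg(count_noise)
  set.seed(seed)
  tx <- traits$taxa
  comm <- tibble::as_tibble(communities) |>
    dplyr::left_join(tx[c("taxon_id", "lw_form", "lw_a", "lw_b",
                          "base_width_ratio")],
                     by = "taxon_id")
  meso_area <- pi * (mesocosm_diameter / 2)^2

  fauna <- comm[comm$fauna_class != "nematode", ]
  ratio <- vapply(fauna$fauna_class, function(cl) {
    core <- cores[[cl]]
    core$n_cores * pi * (core$diameter / 2)^2 / meso_area
  }, numeric(1))
  expected <- fauna$density * ratio
  counts <- if (count_noise == "poisson") rpois(length(expected), expected) else expected
  n_meas <- pmin(ceiling(counts), max_measured)
  meas <- purrr::pmap(
    list(n_meas, fauna$mean_body_mass, fauna$lw_form, fauna$lw_a, fauna$lw_b,
         fauna$base_width_ratio),
    function(n, mbar, form, a, b, wr) {
      if (n == 0) return(list(lengths = "", widths = ""))
      # draw individual masses around the population mean (mean-one noise)
      sdl <- sqrt(log(1 + 0.2^2))
      masses <- mbar * exp(rnorm(n, -sdl^2 / 2, sdl))
      if (form == "power") {
        L <- (masses / a)^(1 / b)
        list(lengths = paste(signif(L, 8), collapse = ";"), widths = "")
      } else { # length_width with W = wr * L
        L <- (masses / (a * wr^(2 * b)))^(1 / (3 * b))
        list(lengths = paste(signif(L, 8), collapse = ";"),
             widths = paste(signif(wr * L, 8), collapse = ";"))
      }
    })
  fauna_samples <- tibble::tibble(
    mesocosm_id = fauna$mesocosm_id,
    taxon_id = fauna$taxon_id,
    count = counts,
    lengths = purrr::map_chr(meas, "lengths"),
    widths = purrr::map_chr(meas, "widths"))

  nema <- comm[comm$fauna_class == "nematode", ]
  nema_samples <- NULL
  nematode_soil <- NULL
  if (nrow(nema) > 0) {
    core <- cores$nematode
    soil <- nema |>
      dplyr::group_by(.data$mesocosm_id) |>
      dplyr::summarise(total_density = sum(.data$density), .groups = "drop") |>
      dplyr::mutate(
        fresh_soil_mass = 20,
        dry_fraction = pmin(pmax(rnorm(dplyr::n(), 0.8, 0.03), 0.6), 0.95),
        dry_soil_density = pmin(pmax(rnorm(dplyr::n(), 1.2, 0.05), 1.0), 1.5))
    volume <- meso_area * core$depth
    soil$total_count_exp <- soil$total_density * soil$fresh_soil_mass *
      soil$dry_fraction / (soil$dry_soil_density * volume)
    soil$total_count <- if (count_noise == "poisson") {
      rpois(nrow(soil), soil$total_count_exp)
    } else {
      soil$total_count_exp
    }
    nema_samples <- nema |>
      dplyr::group_by(.data$mesocosm_id) |>
      dplyr::group_map(function(df, key) {
        tot <- soil$total_count[soil$mesocosm_id == key$mesocosm_id]
        p <- df$density / sum(df$density)
        ident <- if (count_noise == "poisson") {
          n_id <- min(max_identified, floor(tot))
          if (n_id > 0) as.vector(rmultinom(1, n_id, p)) else rep(0, nrow(df))
        } else {
          min(max_identified, tot) * p
        }
        tibble::tibble(mesocosm_id = key$mesocosm_id, taxon_id = df$taxon_id,
                       count = ident, lengths = "", widths = "")
      }) |>
      dplyr::bind_rows()
    nematode_soil <- dplyr::select(soil, "mesocosm_id", "total_count",
                                   "fresh_soil_mass", "dry_fraction",
                                   "dry_soil_density")
  }

  list(samples = dplyr::bind_rows(fauna_samples, nema_samples) |>
         dplyr::arrange(.data$mesocosm_id, .data$taxon_id),
       nematode_soil = nematode_soil)
}

#' One-call synthetic experiment
#'
#' @inheritParams synthetic_communities
#' @param samples if `TRUE`, also render raw sample records.
#' @return List: `design`, `traits`, `communities` (the generator's ground
#'   truth), and when requested `samples` + `nematode_soil`.
#' @export
synthetic_experiment <- function(seed = 1, design = experiment_design(),
                                 traits = synthetic_traits(),
                                 effects = effect_config(),
                                 samples = FALSE) {
  comm <- synthetic_communities(design, traits, effects, seed = seed)
  out <- list(design = design, traits = traits, communities = comm)
  if (samples) {
    out <- c(out, generate_samples(comm, traits, seed = seed + 1))
  }
  out
}
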