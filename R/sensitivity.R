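#' Sensitivity to cross-mesocosm body-mass variation
#'
#' Replaces every population's mean body mass by that taxon's average across
#' all mesocosms (density-weighted by default, so heavily sampled mesocosms
#' contribute more), and recomputes biomass. Re-running the flux pipeline on
#' the result isolates the contribution of within-taxon body-mass shifts:
#' differences that persist are attributable to compositional (abundance)
#' changes alone.
#'
#' @param populations populations tibble ([build_communities()] format).
#' @param weighted if `TRUE` (default) the cross-mesocosm average is
#'   density-weighted; otherwise unweighted over the mesocosms where the
#'   taxon occurs.
#' @return Populations tibble with shared per-taxon body masses and updated
#'   biomass.
#' @export
sensitivity_fixed_bodymass <- function(populations, weighted = TRUE) {
  pops <- tibble::as_tibble(populations)
  avg <- pops |>
    dplyr::filter(.data$density > 0) |>
    dplyr::group_by(.data$taxon_id) |>
    dplyr::summarise(
      fixed_mass = {
        m <- .data$mean_body_mass
        if (max(m) == min(m)) {
          m[1] # exact fixed point when the mass is already shared
        } else if (weighted) {
          stats::weighted.mean(m, .data$density)
        } else {
          mean(m)
        }
      },
      .groups = "drop")
  pops |>
    dplyr::left_join(avg, by = "taxon_id") |>
    dplyr::mutate(
      mean_body_mass = dplyr::coalesce(.data$fixed_mass,
                                       .data$mean_body_mass),
      biomass = .data$density * .data$mean_body_mass) |>
    dplyr::select(-"fixed_mass")
}

#' Sensitivity to biomass and metabolism perturbations
#'
#' Relaxes the steady-state assumption by applying independent multiplicative
#' lognormal noise (mean 1, given coefficients of variation) to every
#' population's biomass (through its density) and metabolic loss, re-solving
#' the flux balance for each draw.
#'
#' @param populations populations of one or more mesocosms.
#' @param traits a [trait_table()].
#' @param biomass_cv,metabolism_cv coefficients of variation of the
#'   multiplicative noise (>= 0).
#' @param n_draws number of Monte-Carlo draws.
#' @param seed RNG seed (draws are reproducible given the seed).
#' @param config,efficiencies,temperature as in [mesocosm_fluxes()].
#' @return List with `draws` (tibble: draw, mesocosm_id, aggregates) and
#'   `summary` (per mesocosm and function: median and 2.5/97.5 percent
#'   quantiles).
#' @export
sensitivity_perturb <- function(populations, traits, biomass_cv = 0.1,
                                metabolism_cv = 0.1, n_draws = 100,
                                seed = 1, config = diet_config(),
                                efficiencies = assimilation_efficiencies(),
                                temperature = 288.15) {
  stopifnot(biomass_cv >= 0, metabolism_cv >= 0, n_draws >= 1)
  pops <- tibble::as_tibble(populations)
  sd_b <- sqrt(log(1 + biomass_cv^2))
  sd_m <- sqrt(log(1 + metabolism_cv^2))
  groups <- split(pops, pops$mesocosm_id)

  set.seed(seed)
  draws <- purrr::map(seq_len(n_draws), function(d) {
    purrr::imap(groups, function(df, m) {
      n <- nrow(df)
      mult_b <- rlnorm(n, -sd_b^2 / 2, sd_b)
      mult_m <- rlnorm(n, -sd_m^2 / 2, sd_m)
      df$density <- df$density * mult_b # biomass noise via density
      df$biomass <- df$density * df$mean_body_mass
      fr <- .solve_mesocosm(df, m, traits, config, efficiencies,
                            temperature, loss_multiplier = mult_m)
      out <- tibble::as_tibble(as.list(fr$aggregates))
      out$mesocosm_id <- m
      out$draw <- d
      out
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  long <- tidyr::pivot_longer(draws,
                              c("total", "predation", "herbivory",
                                "microbivory", "detritivory"),
                              names_to = "function_name",
                              values_to = "flux")
  summary <- long |>
    dplyr::group_by(.data$mesocosm_id, .data$function_name) |>
    dplyr::summarise(median = stats::median(.data$flux),
                     q025 = quantile(.data$flux, 0.025),
                     q975 = quantile(.data$flux, 0.975),
                     mean = mean(.data$flux),
                     .groups = "drop")
  list(draws = dplyr::relocate(draws, "draw", "mesocosm_id"),
       summary = summary)
}
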