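#' Per-mesocosm energy fluxes for a whole experiment
#'
#' Runs the energetics pipeline for every mesocosm in a populations table:
#' builds the trophic preference matrix, computes population metabolic losses
#' from the trait table's allometric coefficients, solves the steady-state
#' balance and aggregates per-link fluxes into trophic functions.
#'
#' @param populations populations tibble from [build_communities()] (or the
#'   synthetic generator).
#' @param traits a [trait_table()].
#' @param config a [diet_config()].
#' @param efficiencies an [assimilation_efficiencies()] vector.
#' @param temperature system temperature in Kelvin.
#' @param links if `TRUE`, attach a list-column `link_fluxes` of per-link flux
#'   tibbles.
#' @return Tibble with one row per mesocosm: `mesocosm_id`, `total`,
#'   `predation`, `herbivory`, `microbivory`, `detritivory` (J/h per
#'   mesocosm) and `max_residual`.
#' @export
mesocosm_fluxes <- function(populations, traits, config = diet_config(),
                            efficiencies = assimilation_efficiencies(),
                            temperature = 288.15, links = FALSE) {
  pops <- tibble::as_tibble(populations)
  res <- pops |>
    dplyr::group_by(.data$mesocosm_id) |>
    dplyr::group_map(function(df, key) {
      fr <- .solve_mesocosm(df, key$mesocosm_id, traits, config,
                            efficiencies, temperature)
      row <- tibble::as_tibble(as.list(fr$aggregates))
      row$max_residual <- max(fr$residuals)
      row$mesocosm_id <- key$mesocosm_id
      if (links) row$link_fluxes <- list(tidy(fr))
      row
    }) |>
    dplyr::bind_rows() |>
    dplyr::relocate("mesocosm_id")
  res
}

# Solve one mesocosm; loss_multiplier perturbs per-taxon metabolic losses
# (sensitivity analysis).
.solve_mesocosm <- function(df, mesocosm_id, traits, config, efficiencies,
                            temperature, loss_multiplier = NULL) {
  df$mesocosm_id <- mesocosm_id
  keep <- df$density > 0
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0) abort(paste0("empty community: ", mesocosm_id))
  W <- build_preference_matrix(df, traits, config)
  mc <- traits$taxa[match(df$taxon_id, traits$taxa$taxon_id),
                    c("metab_ln_x0", "metab_a", "metab_E")]
  X <- population_metabolic_loss(df$density, df$mean_body_mass,
                                 mc$metab_ln_x0, mc$metab_a, mc$metab_E,
                                 temperature)
  if (!is.null(loss_multiplier)) X <- X * loss_multiplier[keep]
  solve_fluxes(W, setNames(X, df$taxon_id), efficiencies)
}

#' Full analysis of a (synthetic or real) experiment
#'
#' Convenience wrapper: per-mesocosm fluxes plus community metrics, joined to
#' the experimental design — the per-mesocosm response table that the
#' contrast and slope estimators consume.
#'
#' @inheritParams mesocosm_fluxes
#' @param design experimental design tibble with `mesocosm_id`, `block`,
#'   `ecounit`, `history` (see [experiment_design()]).
#' @return Tibble with one row per mesocosm holding design labels, flux
#'   aggregates and community metrics.
#' @export
analyse_experiment <- function(populations, traits, design,
                               config = diet_config(),
                               efficiencies = assimilation_efficiencies(),
                               temperature = 288.15) {
  fl <- mesocosm_fluxes(populations, traits, config, efficiencies,
                        temperature)
  cm <- community_metrics(populations)
  design |>
    tibble::as_tibble() |>
    dplyr::inner_join(fl, by = "mesocosm_id") |>
    dplyr::inner_join(cm, by = "mesocosm_id")
}
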