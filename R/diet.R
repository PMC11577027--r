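#' Quadratic-logistic link-probability model in log10 predator:prey mass ratio
#'
#' The probability that a predator consumes prey of a given size follows a
#' hump-shaped curve in the log10 body-mass ratio r = log10(M_pred / M_prey):
#' p = logistic(b0 + b1 r + b2 r^2), with b2 <= 0 so the curve is unimodal and
#' the optimum sits at r* = -b1 / (2 b2).
#'
#' The default coefficients are illustrative (optimum near a predator:prey
#' mass ratio of 10^1.5); coefficients estimated from interaction databases
#' should be supplied for real analyses.
#'
#' @param b0,b1,b2 model coefficients; `b2` must be <= 0.
#' @return A `link_model_coeffs` list.
#' @export
link_model_coeffs <- function(b0 = -1, b1 = 1.5, b2 = -0.5) {
  if (b2 > 0) abort("b2 must be <= 0 (unimodal link probability)")
  structure(list(b0 = b0, b1 = b1, b2 = b2), class = "link_model_coeffs")
}

#' @rdname link_model_coeffs
#' @param pred_mass,prey_mass body masses in mg (vectorized).
#' @param coeffs a [link_model_coeffs()].
#' @return `link_probability()`: probability in \[0, 1\].
#' @export
#' @examples
#' link_probability(10, 1, link_model_coeffs(0, 1, 0)) # logistic(1)
link_probability <- function(pred_mass, prey_mass, coeffs = link_model_coeffs()) {
  if (any(pred_mass <= 0) || any(prey_mass <= 0)) {
    abort("body masses must be positive")
  }
  r <- log10(pred_mass / prey_mass)
  stats::plogis(coeffs$b0 + coeffs$b1 * r + coeffs$b2 * r^2)
}

#' Configuration of the diet-refinement modifiers
#'
#' Animal-prey weights are the product of the mass-ratio link probability, an
#' agility modifier, a defense modifier, the stratum overlap and the prey's
#' relative biomass. Agile prey are discounted by
#' `(1 - agility) * agility_strength + (1 - agility_strength)` (so
#' `agility_strength = 0` switches the modifier off and `1` makes weight
#' proportional to 1 - agility); defended prey are multiplied by
#' `defense_factor`.
#'
#' @param link_coeffs a [link_model_coeffs()].
#' @param agility_strength weight k of the agility discount, in \[0, 1\].
#' @param defense_factor multiplier applied to defended prey, in (0, 1\].
#' @param overlap 3x3 stratum overlap matrix (see [stratum_overlap()]).
#' @param basal_biomass_scaling if `TRUE`, basal diet fractions are split over
#'   same-type resource nodes proportionally to `pool_biomass`; otherwise
#'   uniformly.
#' @return A `diet_config` list.
#' @export
diet_config <- function(link_coeffs = link_model_coeffs(),
                        agility_strength = 0.5, defense_factor = 0.5,
                        overlap = stratum_overlap(),
                        basal_biomass_scaling = FALSE) {
  stopifnot(agility_strength >= 0, agility_strength <= 1,
            defense_factor > 0, defense_factor <= 1,
            identical(dim(overlap), c(3L, 3L)))
  structure(list(link_coeffs = link_coeffs,
                 agility_strength = agility_strength,
                 defense_factor = defense_factor,
                 overlap = overlap,
                 basal_biomass_scaling = basal_biomass_scaling),
            class = "diet_config")
}

#' Refined animal-diet weights of one consumer over a prey pool
#'
#' @param consumer one-row data frame with `taxon_id`, `mean_body_mass` and
#'   the consumer's `stratum`.
#' @param prey data frame of candidate prey with `taxon_id`,
#'   `mean_body_mass`, `biomass`, `agility`, `defended`, `stratum`.
#' @param config a [diet_config()].
#' @return Named numeric vector of nonnegative weights over prey taxa
#'   (self-predation weight forced to 0).
#' @export
refine_animal_diet <- function(consumer, prey, config = diet_config()) {
  if (nrow(prey) == 0) return(setNames(numeric(), character()))
  p_link <- link_probability(consumer$mean_body_mass, prey$mean_body_mass,
                             config$link_coeffs)
  k <- config$agility_strength
  agility_mod <- (1 - prey$agility) * k + (1 - k)
  defense_mod <- ifelse(prey$defended, config$defense_factor, 1)
  overlap <- config$overlap[cbind(match(consumer$stratum, .strata),
                                  match(prey$stratum, .strata))]
  w <- p_link * agility_mod * defense_mod * overlap * prey$biomass
  w[prey$taxon_id == consumer$taxon_id] <- 0 # no cannibalism at taxon level
  setNames(w, prey$taxon_id)
}

#' Build the column-stochastic trophic preference matrix of one mesocosm
#'
#' Nodes are the mesocosm's animal taxa followed by the basal resource nodes.
#' Entry `W[i, j]` is the proportion of consumer j's diet taken from resource
#' i. For each consumer the general diet fractions allocate mass among the
#' four components (animal, plant, microbe, detritus); the animal component is
#' distributed over prey taxa proportionally to [refine_animal_diet()]
#' weights, and each basal component over the matching resource nodes
#' (uniformly, or by pool biomass when configured). A component that is
#' locally absent (no prey with positive weight, or no node of that type) has
#' its fraction redistributed proportionally over the remaining components, so
#' every consumer column sums to exactly 1. Basal nodes have all-zero columns;
#' the diagonal is zero.
#'
#' @param populations populations of one mesocosm ([build_communities()]
#'   rows).
#' @param traits a [trait_table()].
#' @param config a [diet_config()].
#' @return A `preference_matrix`: square numeric matrix with attributes
#'   `node_type` (one of animal/plant/microbe/detritus per node) and
#'   `mesocosm_id`.
#' @export
build_preference_matrix <- function(populations, traits,
                                    config = diet_config()) {
  stopifnot(inherits(traits, "trait_table"))
  pops <- tibble::as_tibble(populations)
  if (length(unique(pops$mesocosm_id %||% "")) > 1) {
    abort("populations must belong to a single mesocosm")
  }
  if (anyDuplicated(pops$taxon_id)) abort("duplicated taxon within mesocosm")
  unknown <- validate_against_samples(traits, pops$taxon_id)
  if (length(unknown) > 0) {
    abort(paste0("taxa missing from trait table: ",
                 paste(unknown, collapse = ", ")))
  }
  tx <- dplyr::left_join(pops,
                         traits$taxa[c("taxon_id", "frac_animal", "frac_plant",
                                       "frac_microbe", "frac_detritus",
                                       "agility", "defended", "stratum")],
                         by = "taxon_id")
  res <- traits$resources
  nodes <- c(tx$taxon_id, res$node_id)
  node_type <- c(rep("animal", nrow(tx)), res$resource_type)
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))

  basal_rows <- lapply(.resource_types, function(rt) which(node_type == rt))
  names(basal_rows) <- .resource_types
  basal_share <- lapply(.resource_types, function(rt) {
    rows <- which(res$resource_type == rt)
    if (length(rows) == 0) return(numeric())
    if (config$basal_biomass_scaling) {
      pb <- res$pool_biomass[rows]
      if (any(is.na(pb) | pb <= 0)) {
        abort(paste0("basal biomass scaling enabled but pool_biomass not ",
                     "positive for ", rt))
      }
      pb / sum(pb)
    } else {
      rep(1 / length(rows), length(rows))
    }
  })
  names(basal_share) <- .resource_types

  for (j in seq_len(nrow(tx))) {
    cons <- tx[j, ]
    frac <- c(animal = cons$frac_animal, plant = cons$frac_plant,
              microbe = cons$frac_microbe, detritus = cons$frac_detritus)
    frac <- frac / sum(frac)

    prey_w <- if (frac["animal"] > 0) {
      refine_animal_diet(cons, tx, config)
    } else {
      setNames(numeric(nrow(tx)), tx$taxon_id)
    }
    available <- c(
      animal = frac["animal"] > 0 && sum(prey_w) > 0,
      plant = frac["plant"] > 0 && length(basal_rows$plant) > 0,
      microbe = frac["microbe"] > 0 && length(basal_rows$microbe) > 0,
      detritus = frac["detritus"] > 0 && length(basal_rows$detritus) > 0)
    if (!any(available & frac > 0)) {
      abort(paste0("consumer ", cons$taxon_id,
                   " has no available resource in this mesocosm"))
    }
    frac[!available] <- 0
    frac <- frac / sum(frac) # redistribute locally absent components

    col <- numeric(n)
    if (frac["animal"] > 0) {
      col[seq_len(nrow(tx))] <- frac["animal"] * prey_w / sum(prey_w)
    }
    for (rt in .resource_types) {
      if (frac[rt] > 0) {
        col[basal_rows[[rt]]] <- frac[rt] * basal_share[[rt]]
      }
    }
    W[, j] <- col / sum(col)
  }

  structure(W, node_type = setNames(node_type, nodes),
            mesocosm_id = unique(pops$mesocosm_id %||% NA_character_),
            class = c("preference_matrix", "matrix", "array"))
}
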