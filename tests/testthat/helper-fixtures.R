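# Small hand-built trait tables and communities used across tests.

tiny_traits <- function(resources = default_resources()) {
  trait_table(tibble::tibble(
    taxon_id = c("worm", "springtail", "mite", "beetle"),
    fauna_class = c("macrofauna", "mesofauna", "mesofauna", "macrofauna"),
    frac_animal = c(0, 0, 1, 0.5),
    frac_plant = c(0, 0.1, 0, 0),
    frac_microbe = c(0.1, 0.5, 0, 0),
    frac_detritus = c(0.9, 0.4, 0, 0.5),
    agility = c(0.2, 0.8, 0.7, 0.5),
    defended = c(FALSE, FALSE, FALSE, TRUE),
    stratum = c("euedaphic", "hemiedaphic", "hemiedaphic", "epigeic"),
    metab_ln_x0 = 23.055, metab_a = 0.695, metab_E = 0.686,
    lw_form = c("length_width", "power", "power", "length_width"),
    lw_a = c(2, 0.04, 0.05, 1.5),
    lw_b = c(0.9, 2.5, 2.4, 0.95),
    fixed_body_mass = NA_real_
  ), resources)
}

# one-row trait table builder for error-path tests
one_taxon <- function(...) {
  defaults <- list(
    taxon_id = "t1", fauna_class = "mesofauna",
    frac_animal = 0, frac_plant = 0, frac_microbe = 0.5, frac_detritus = 0.5,
    agility = 0.5, defended = FALSE, stratum = "hemiedaphic",
    metab_ln_x0 = 0, metab_a = 0, metab_E = 0,
    lw_form = "power", lw_a = 1, lw_b = 1, fixed_body_mass = NA_real_)
  args <- utils::modifyList(defaults, list(...))
  tibble::as_tibble(args)
}

# a random but always-feasible community of n_animal taxa for property tests
random_community <- function(n_animal, mesocosm_id = "m1") {
  frac_animal <- runif(n_animal, 0, 0.6) # keeps the flux balance feasible
  rest <- matrix(runif(n_animal * 3), n_animal)
  rest <- rest / rowSums(rest) * (1 - frac_animal)
  taxa <- tibble::tibble(
    taxon_id = sprintf("tx%02d", seq_len(n_animal)),
    fauna_class = sample(c("macrofauna", "mesofauna"), n_animal, TRUE),
    frac_animal = frac_animal,
    frac_plant = rest[, 1], frac_microbe = rest[, 2],
    frac_detritus = rest[, 3],
    agility = runif(n_animal), defended = runif(n_animal) < 0.3,
    stratum = sample(c("epigeic", "hemiedaphic", "euedaphic"), n_animal, TRUE),
    metab_ln_x0 = 23.055, metab_a = 0.695, metab_E = 0.686,
    lw_form = "power", lw_a = 0.05, lw_b = 2.5,
    fixed_body_mass = NA_real_)
  pops <- tibble::tibble(
    mesocosm_id = mesocosm_id,
    taxon_id = taxa$taxon_id,
    fauna_class = taxa$fauna_class,
    density = exp(runif(n_animal, 0, 8)),
    mean_body_mass = exp(runif(n_animal, log(1e-3), log(1e2))))
  pops$biomass <- pops$density * pops$mean_body_mass
  list(traits = trait_table(taxa), populations = pops)
}
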