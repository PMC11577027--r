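test_that("link probability follows the quadratic logistic in log10 PPMR", {
  c1 <- link_model_coeffs(0, 0, -1)
  expect_equal(link_probability(1, 1, c1), 0.5)
  for (r in c(0.3, 1, 2.7)) {
    expect_equal(link_probability(10^r, 1, c1), link_probability(1, 10^r, c1))
  }
  expect_equal(link_probability(10, 1, link_model_coeffs(0, 1, 0)),
               stats::plogis(1))
  expect_error(link_probability(-1, 1), "positive")
  expect_error(link_model_coeffs(0, 0, 1), "b2")
})

test_that("diet refinement multiplies the independent modifiers", {
  cons <- tibble::tibble(taxon_id = "pred", mean_body_mass = 10,
                         stratum = "hemiedaphic")
  prey_base <- tibble::tibble(
    taxon_id = c("a", "b"), mean_body_mass = 1, biomass = c(2, 1),
    agility = 0.5, defended = FALSE, stratum = "hemiedaphic")
  cfg <- diet_config()
  w <- refine_animal_diet(cons, prey_base, cfg)
  expect_equal(unname(w["a"] / w["b"]), 2) # linear in prey biomass

  prey2 <- dplyr::mutate(prey_base, biomass = 1,
                         stratum = c("hemiedaphic", "euedaphic"))
  cfg0 <- diet_config(overlap = stratum_overlap(adjacent = 0))
  w2 <- refine_animal_diet(cons, prey2, cfg0)
  expect_equal(unname(w2["b"]), 0) # non-overlapping stratum

  prey3 <- dplyr::mutate(prey_base, biomass = 1, defended = c(FALSE, TRUE))
  w3 <- refine_animal_diet(cons, prey3, diet_config(defense_factor = 0.5))
  expect_equal(unname(w3["b"] / w3["a"]), 0.5)

  # self-predation is excluded
  self <- dplyr::mutate(prey_base, taxon_id = c("pred", "b"))
  expect_equal(unname(refine_animal_diet(cons, self, cfg)["pred"]), 0)
})

test_that("preference columns allocate diet fractions as specified", {
  tr <- trait_table(dplyr::bind_rows(
    one_taxon(taxon_id = "worm", frac_microbe = 0, frac_detritus = 1),
    one_taxon(taxon_id = "p1", frac_animal = 0, frac_microbe = 1,
              frac_detritus = 0),
    one_taxon(taxon_id = "p2", frac_animal = 0, frac_microbe = 1,
              frac_detritus = 0),
    one_taxon(taxon_id = "omni", frac_animal = 0.5, frac_microbe = 0,
              frac_detritus = 0.5)))
  pops_worm <- tibble::tibble(mesocosm_id = "m", taxon_id = "worm",
                              density = 1, mean_body_mass = 1, biomass = 1)
  W_worm <- build_preference_matrix(pops_worm, tr)
  # pure detritivore: all mass on the detritus node
  expect_equal(unname(W_worm["detritus", "worm"]), 1)

  pops <- tibble::tibble(
    mesocosm_id = "m",
    taxon_id = c("p1", "p2", "omni"),
    density = 1,
    mean_body_mass = c(0.1, 0.1, 10), # p1, p2 identical prey
    biomass = c(0.1, 0.1, 10))
  W <- build_preference_matrix(pops, tr)
  # omnivore with two identical prey: (0.25, 0.25, 0.5)
  expect_equal(unname(W[c("p1", "p2", "detritus"), "omni"]),
               c(0.25, 0.25, 0.5))
  expect_equal(sum(W[, "omni"]), 1)
})

test_that("locally absent diet components are redistributed", {
  tr <- trait_table(one_taxon(taxon_id = "omni", frac_animal = 0.4,
                              frac_microbe = 0.3, frac_detritus = 0.3))
  pops <- tibble::tibble(mesocosm_id = "m", taxon_id = "omni", density = 1,
                         mean_body_mass = 1, biomass = 1)
  W <- build_preference_matrix(pops, tr) # no prey in the mesocosm
  expect_equal(sum(W[, "omni"]), 1)
  expect_equal(unname(W[c("microbe", "detritus"), "omni"]), c(0.5, 0.5))

  # a consumer whose only resource type has no node errors by name
  tr2 <- trait_table(one_taxon(taxon_id = "herb", frac_plant = 1,
                               frac_microbe = 0, frac_detritus = 0),
                     resources = default_resources()[2:3, ])
  pops2 <- dplyr::mutate(pops, taxon_id = "herb")
  expect_error(build_preference_matrix(pops2, tr2), "herb")
})

test_that("columns are stochastic and invariant to scaling and null prey", {
  set.seed(31)
  for (i in 1:20) {
    rc <- random_community(sample(3:15, 1))
    W <- build_preference_matrix(rc$populations, rc$traits)
    nt <- attr(W, "node_type")
    cons <- nt == "animal"
    expect_equal(unname(colSums(W[, cons, drop = FALSE])),
                 rep(1, sum(cons)), tolerance = 1e-12)
    expect_true(all(colSums(W[, !cons, drop = FALSE]) == 0))
    expect_true(all(diag(W) == 0))
    expect_true(all(W >= 0))

    # only relative prey biomass matters
    scaled <- dplyr::mutate(rc$populations,
                            density = density * 17.3,
                            biomass = density * mean_body_mass)
    expect_equal(unclass(build_preference_matrix(scaled, rc$traits)),
                 unclass(W), ignore_attr = TRUE)
  }
})

test_that("removing a zero-weight prey leaves the matrix unchanged", {
  tr_full <- trait_table(dplyr::bind_rows(
    one_taxon(taxon_id = "pred", frac_animal = 1, frac_microbe = 0,
              frac_detritus = 0, stratum = "epigeic"),
    one_taxon(taxon_id = "prey1", stratum = "epigeic"),
    one_taxon(taxon_id = "ghost", stratum = "euedaphic")))
  pops <- tibble::tibble(
    mesocosm_id = "m", taxon_id = c("pred", "prey1", "ghost"),
    density = 1, mean_body_mass = c(10, 1, 1), biomass = c(10, 1, 1))
  cfg <- diet_config(overlap = stratum_overlap(adjacent = 0))
  W_full <- build_preference_matrix(pops, tr_full, cfg)
  expect_equal(unname(W_full["ghost", "pred"]), 0)
  W_red <- build_preference_matrix(pops[1:2, ], tr_full, cfg)
  common <- c("pred", "prey1", "plant", "microbe", "detritus")
  expect_equal(unclass(W_full)[common, common][, c("pred", "prey1")],
               unclass(W_red)[common, c("pred", "prey1")])
})
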