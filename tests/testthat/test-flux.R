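make_web <- function(links, animal, basal) {
  # links: data.frame(resource, consumer, w)
  nodes <- c(names(animal), names(basal))
  W <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(links))) {
    W[links$resource[i], links$consumer[i]] <- links$w[i]
  }
  attr(W, "node_type") <- c(animal, basal)
  W
}

test_that("metabolic rates follow the allometric Arrhenius regression", {
  expect_equal(individual_metabolic_rate(5, ln_x0 = 0, a = 0, E = 0), 1)
  expect_equal(individual_metabolic_rate(exp(1), ln_x0 = 0, a = 1, E = 0),
               exp(1))
  m <- c(0.1, 1, 10)
  r <- individual_metabolic_rate(m, ln_x0 = 2, a = 0.7, E = 0.69)
  expect_true(all(diff(r) > 0))
  # closed form including the temperature term
  expect_equal(r, exp(2 + 0.7 * log(m) - 0.69 / (8.617333e-5 * 288.15)))
  expect_error(individual_metabolic_rate(-1, 0, 0, 0), "positive")
})

test_that("population losses are individual rate times density", {
  expect_equal(population_metabolic_loss(0, 10, 5, 1, 1), 0)
  expect_equal(population_metabolic_loss(10, 1, log(0.5), 0, 0), 5)
  # with a = 0 the loss is mass-independent
  expect_equal(population_metabolic_loss(7, 2, 1.3, 0, 0),
               population_metabolic_loss(7, 1, 1.3, 0, 0))
})

test_that("single-consumer web matches the closed form", {
  W <- make_web(data.frame(resource = "det", consumer = "worm", w = 1),
                c(worm = "animal"), c(det = "detritus"))
  fr <- solve_fluxes(W, c(worm = 1))
  expect_equal(unname(fr$consumption), 1 / 0.158)
  expect_equal(fr$aggregates[["total"]], 6.3291, tolerance = 1e-4)
  expect_equal(fr$aggregates[["detritivory"]], fr$aggregates[["total"]])
  expect_equal(fr$aggregates[["predation"]], 0)
})

test_that("two-level chain matches the closed form", {
  W <- make_web(data.frame(resource = c("det", "worm"),
                           consumer = c("worm", "pred"), w = 1),
                c(worm = "animal", pred = "animal"), c(det = "detritus"))
  fr <- solve_fluxes(W, c(worm = 1, pred = 1))
  G_p <- 1 / 0.906
  G_d <- (1 + G_p) / 0.158
  expect_equal(unname(fr$consumption[c("pred", "worm")]), c(G_p, G_d))
  expect_equal(fr$aggregates[["predation"]], G_p)
  expect_equal(fr$aggregates[["detritivory"]], G_d)
  expect_equal(fr$aggregates[["total"]], G_p + G_d)
  # zero losses give the trivial steady state
  fr0 <- solve_fluxes(W, c(worm = 0, pred = 0))
  expect_true(all(fr0$fluxes == 0))
})

test_that("aggregation decomposes the total exactly and ignores node order", {
  set.seed(41)
  rc <- random_community(8)
  W <- build_preference_matrix(rc$populations, rc$traits)
  X <- setNames(runif(8, 0.1, 2), rc$populations$taxon_id)
  fr <- solve_fluxes(W, X)
  agg <- fr$aggregates
  expect_equal(sum(agg[c("predation", "herbivory", "microbivory",
                         "detritivory")]),
               agg[["total"]])
  perm <- sample(nrow(fr$fluxes))
  agg_perm <- aggregate_fluxes(fr$fluxes[perm, perm],
                               fr$node_type[perm])
  expect_equal(agg_perm, agg)
})

test_that("balance, additivity, equivariance and monotonicity hold on random webs", {
  set.seed(42)
  for (i in 1:40) {
    web <- random_web(30)
    fr <- solve_fluxes(web$W, web$X)
    expect_lt(max(fr$residuals), 1e-8)
    expect_true(all(fr$fluxes >= 0))
    agg <- fr$aggregates
    expect_equal(sum(agg[-1]), agg[["total"]], tolerance = 1e-14)

    # scale equivariance
    fr_c <- solve_fluxes(web$W, 3.7 * web$X)
    expect_equal(fr_c$aggregates, 3.7 * agg)

    # monotonicity: increasing one loss weakly increases total flux
    X2 <- web$X
    j <- sample(length(X2), 1)
    X2[j] <- X2[j] * 2
    expect_gte(solve_fluxes(web$W, X2)$aggregates[["total"]],
               agg[["total"]])
  }
})

test_that("direct solve agrees with the fixed-point oracle", {
  set.seed(43)
  for (i in 1:40) {
    web <- random_web(30)
    fr <- solve_fluxes(web$W, web$X)
    G_oracle <- oracle_fluxes(web$W, web$X)
    expect_equal(max(abs(fr$consumption - G_oracle) /
                       pmax(G_oracle, 1e-12)), 0, tolerance = 1e-8)
  }
})

test_that("smaller bodies at fixed biomass increase flux", {
  # mass exponent < 1: halving mass while doubling density raises losses
  tr <- trait_table(one_taxon(taxon_id = "worm", frac_microbe = 0,
                              frac_detritus = 1,
                              metab_ln_x0 = 2, metab_a = 0.695))
  pops <- tibble::tibble(mesocosm_id = "m", taxon_id = "worm",
                         density = 10, mean_body_mass = 4, biomass = 40)
  small <- tibble::tibble(mesocosm_id = "m", taxon_id = "worm",
                          density = 20, mean_body_mass = 2, biomass = 40)
  f_big <- mesocosm_fluxes(pops, tr)
  f_small <- mesocosm_fluxes(small, tr)
  expect_gt(f_small$total, f_big$total)
})

test_that("degenerate and infeasible webs raise informative errors", {
  # two obligate mutual predators: no feasible steady state
  W <- make_web(data.frame(resource = c("a", "b"), consumer = c("b", "a"),
                           w = 1),
                c(a = "animal", b = "animal"), c(det = "detritus"))
  expect_error(solve_fluxes(W, c(a = 1, b = 1)),
               "infeasible|degenerate")
  # non-stochastic consumer column
  W2 <- make_web(data.frame(resource = "det", consumer = "worm", w = 0.5),
                 c(worm = "animal"), c(det = "detritus"))
  expect_error(solve_fluxes(W2, c(worm = 1)), "sum to 1")
  expect_error(solve_fluxes(W, c(a = -1, b = 1)), "nonnegative")
})
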