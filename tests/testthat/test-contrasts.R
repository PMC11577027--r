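# minimal balanced design frame for direct construction of responses
toy_design <- function() experiment_design()

test_that("identical treatment arms give null contrasts containing zero", {
  des <- toy_design()
  base <- exp(rnorm(24, 0, 0.2))[match(des$ecounit, unique(des$ecounit))]
  dat <- dplyr::mutate(des, y = base) # all four arms identical per EcoUnit
  pc <- pairwise_contrasts(dat, "y", n_boot = 500, seed = 2)
  tab <- tidy(pc)
  expect_equal(tab$estimate, rep(0, nrow(tab)))
  expect_true(all(!tab$excludes_zero_95))
  expect_true(all(tab$decision == "unclear"))
})

test_that("four levels yield six pairwise contrasts plus two pooled margins", {
  des <- toy_design()
  dat <- dplyr::mutate(des, y = exp(rnorm(96)))
  pc <- pairwise_contrasts(dat, "y", n_boot = 200, seed = 1)
  expect_equal(nrow(tidy(pc)), 8)
  expect_equal(sum(!grepl("pooled", tidy(pc)$contrast)), 6)
  pc2 <- pairwise_contrasts(dat, "y", n_boot = 200, seed = 1, margins = FALSE)
  expect_equal(nrow(tidy(pc2)), 6)
  # determinism under the seed
  pc3 <- pairwise_contrasts(dat, "y", n_boot = 200, seed = 1)
  expect_identical(tidy(pc), tidy(pc3))
})

test_that("contrasts are antisymmetric draw by draw", {
  des <- toy_design()
  set.seed(77)
  dat <- dplyr::mutate(des, y = exp(rnorm(96)))
  fwd <- pairwise_contrasts(dat, "y", n_boot = 300, seed = 5,
                            margins = FALSE)
  rev_dat <- dplyr::mutate(
    dat, history = factor(as.character(history),
                          rev(c("none", "plant", "soil", "soil_plant"))))
  bwd <- pairwise_contrasts(rev_dat, "y", n_boot = 300, seed = 5,
                            margins = FALSE)
  expect_equal(fwd$draws[, "soil_plant - none"],
               -bwd$draws[, "none - soil_plant"])
  expect_equal(fwd$draws[, "soil - plant"], -bwd$draws[, "plant - soil"])
})

test_that("an imposed log-difference on the response is recovered", {
  des <- toy_design()
  tr <- synthetic_traits()
  eff <- effect_config(soil_biomass_multiplier = exp(0.7),
                       soil_cwm_multiplier = 1)
  comm <- synthetic_communities(des, tr, eff, seed = 71)
  cm <- dplyr::inner_join(des, community_metrics(comm), by = "mesocosm_id")
  pc <- pairwise_contrasts(cm, "biomass", n_boot = 1000, seed = 72)
  s <- tidy(pc)[tidy(pc)$contrast == "soil history (pooled)", ]
  expect_equal(s$estimate, 0.7, tolerance = 0.25)
  expect_true(s$excludes_zero_95)
})

test_that("missing treatment cells and bad responses are rejected", {
  des <- toy_design()
  dat <- dplyr::mutate(des, y = exp(rnorm(96)))
  expect_error(pairwise_contrasts(dat[dat$history != "soil", ], "y"),
               "missing treatment cell|four history levels")
  expect_error(pairwise_contrasts(dplyr::mutate(dat, y = y - 5), "y"),
               "positive")
  expect_error(pairwise_contrasts(dat, "nope"), "nope")
})

test_that("the decision rule separates clear, marginal and unclear", {
  # reference interval patterns
  ex95 <- c(TRUE, FALSE, FALSE)
  ex90 <- c(TRUE, TRUE, FALSE)
  expect_equal(interval_decision(ex95, ex90),
               c("clear", "marginal", "unclear"))
  # from interval endpoints as reported
  lower_95 <- c(0.44, -0.87, -0.2); upper_95 <- c(0.98, 0.05, 0.3)
  lower_90 <- c(0.50, -0.80, -0.1); upper_90 <- c(0.90, -0.01, 0.2)
  e95 <- lower_95 > 0 | upper_95 < 0
  e90 <- lower_90 > 0 | upper_90 < 0
  expect_equal(interval_decision(e95, e90),
               c("clear", "marginal", "unclear"))
})

test_that("exact proportionality gives a log-log slope of one", {
  des <- toy_design()
  set.seed(81)
  b <- exp(rnorm(96, 8, 0.5))
  dat <- dplyr::mutate(des, biomass = b, cwm_body_mass = exp(rnorm(96)),
                       total = 3.2 * b)
  sl <- structure_slopes(dat, "total", predictors = "biomass",
                         n_boot = 300, seed = 6)
  tab <- tidy(sl)
  expect_equal(tab$estimate, 1, tolerance = 1e-10)
  expect_true(all(abs(c(tab$lower_95, tab$upper_95) - 1) < 1e-8))
})

test_that("a null predictor's slope interval covers zero", {
  des <- toy_design()
  set.seed(82)
  dat <- dplyr::mutate(des, total = exp(rnorm(96)),
                       cwm_body_mass = exp(rnorm(96)))
  sl <- tidy(structure_slopes(dat, "total", predictors = "cwm_body_mass",
                              n_boot = 500, seed = 7))
  expect_true(sl$lower_95 <= 0 & 0 <= sl$upper_95)
  expect_error(structure_slopes(dplyr::mutate(dat, cwm_body_mass = 2),
                                "total", predictors = "cwm_body_mass"),
               "zero-variance")
})

test_that("a generator-built slope on log CWM is recovered", {
  # responses built directly over the design: log flux = -0.3 log cwm + noise
  des <- toy_design()
  set.seed(83)
  cover <- replicate(20, {
    cwm <- exp(rnorm(96, 0, 1))
    tot <- exp(-0.3 * log(cwm) + rnorm(96, 0, 0.15))
    dat <- dplyr::mutate(des, total = tot, cwm_body_mass = cwm)
    s <- tidy(structure_slopes(dat, "total", predictors = "cwm_body_mass",
                               n_boot = 400, seed = sample.int(1e6, 1)))
    s$lower_95 <= -0.3 & -0.3 <= s$upper_95
  })
  expect_gte(mean(cover), 0.8)
})
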