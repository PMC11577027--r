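#' Hierarchical bootstrap contrasts of the community-history treatments
#'
#' Estimates pairwise differences among the four community-history levels
#' (and, optionally, the pooled soil- and plant-history main contrasts) with
#' a nonparametric bootstrap that respects the nesting of the design: each
#' draw resamples blocks with replacement, then EcoUnits within each sampled
#' block with replacement, and recomputes treatment means from the resampled
#' EcoUnits' mesocosms. Percentile intervals at 95% and 90% are reported
#' together with the zero-exclusion decision: `clear` when the 95% interval
#' excludes 0, `marginal` when only the 90% interval does, `unclear`
#' otherwise.
#'
#' @param data per-mesocosm tibble holding the response and the design
#'   columns `block`, `ecounit`, `history` (levels `none`, `plant`, `soil`,
#'   `soil_plant`), e.g. from [analyse_experiment()].
#' @param response name of the response column.
#' @param transform `"log"` (default; responses must be positive) or
#'   `"identity"`. Differences are reported on the analysis scale.
#' @param n_boot number of bootstrap draws (>= 1000 recommended).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param margins if `TRUE`, also report the pooled `soil` and `plant`
#'   main-effect contrasts (with vs without the history component).
#' @return A `history_contrasts` object; `tidy()` returns the contrast table
#'   (`contrast`, `estimate`, interval bounds, exclusion flags, `decision`),
#'   `glance()` the fit metadata.
#' @export
pairwise_contrasts <- function(data, response, transform = c("log", "identity"),
                               n_boot = 1000, seed = 1, margins = TRUE) {
  transform <- match.arg(transform)
  prep <- .prep_hierarchy(data, response, transform)
  lev <- colnames(prep$Y)

  idx <- .boot_ecounits(prep$eu_block, n_boot, seed)
  means_obs <- colMeans(prep$Y)
  boot_means <- .cell_means(prep$Y, idx) # n_boot x 4

  pairs <- utils::combn(lev, 2)
  cons <- purrr::map2(pairs[1, ], pairs[2, ], function(a, b) {
    list(name = paste0(b, " - ", a),
         obs = means_obs[[b]] - means_obs[[a]],
         draws = boot_means[, b] - boot_means[, a])
  })
  if (margins) {
    if (!all(c("none", "plant", "soil", "soil_plant") %in% lev)) {
      abort("pooled margins require the four history levels")
    }
    soil_lev <- c("soil", "soil_plant")
    nosoil_lev <- c("none", "plant")
    plant_lev <- c("plant", "soil_plant")
    noplant_lev <- c("none", "soil")
    cons <- c(cons, list(
      list(name = "soil history (pooled)",
           obs = mean(means_obs[soil_lev]) - mean(means_obs[nosoil_lev]),
           draws = rowMeans(boot_means[, soil_lev, drop = FALSE]) -
             rowMeans(boot_means[, nosoil_lev, drop = FALSE])),
      list(name = "plant history (pooled)",
           obs = mean(means_obs[plant_lev]) - mean(means_obs[noplant_lev]),
           draws = rowMeans(boot_means[, plant_lev, drop = FALSE]) -
             rowMeans(boot_means[, noplant_lev, drop = FALSE]))))
  }

  tab <- purrr::map(cons, function(cn) {
    q <- quantile(cn$draws, c(0.025, 0.975, 0.05, 0.95), names = FALSE)
    tibble::tibble(contrast = cn$name, estimate = cn$obs,
                   lower_95 = q[1], upper_95 = q[2],
                   lower_90 = q[3], upper_90 = q[4])
  }) |> dplyr::bind_rows()
  tab$excludes_zero_95 <- tab$lower_95 > 0 | tab$upper_95 < 0
  tab$excludes_zero_90 <- tab$lower_90 > 0 | tab$upper_90 < 0
  tab$decision <- interval_decision(tab$excludes_zero_95, tab$excludes_zero_90)

  draw_mat <- do.call(cbind, purrr::map(cons, "draws"))
  colnames(draw_mat) <- purrr::map_chr(cons, "name")
  structure(list(contrasts = tab,
                 draws = draw_mat,
                 treatment_means = tibble::tibble(
                   history = lev, mean = unname(means_obs),
                   lower_95 = apply(boot_means, 2, quantile, 0.025),
                   upper_95 = apply(boot_means, 2, quantile, 0.975)),
                 response = response, transform = transform,
                 n_boot = n_boot, seed = seed, n = prep$n),
            class = "history_contrasts")
}

#' Zero-exclusion decision rule
#'
#' `clear` when the 95% interval excludes zero, `marginal` when only the 90%
#' interval does, `unclear` otherwise.
#'
#' @param excludes_95,excludes_90 logical vectors (or a `history_contrasts`
#'   table's flags).
#' @return Character vector of decisions.
#' @export
interval_decision <- function(excludes_95, excludes_90) {
  dplyr::case_when(excludes_95 ~ "clear",
                   excludes_90 ~ "marginal",
                   TRUE ~ "unclear")
}

#' Bootstrap slopes of flux on community structure
#'
#' Ordinary least-squares slope of the (log) response on each (log)
#' predictor, with uncertainty from the same block/EcoUnit hierarchical
#' bootstrap as [pairwise_contrasts()]. By default slopes are on the raw
#' log-log scale (so exact proportionality of flux to biomass gives slope 1);
#' set `standardize = TRUE` to z-score each predictor once on the full data,
#' making slopes comparable across predictors.
#'
#' @inheritParams pairwise_contrasts
#' @param response response column name (log-transformed by default).
#' @param predictors character vector of predictor column names
#'   (log-transformed).
#' @param standardize z-score the (log) predictors before fitting.
#' @return A `structure_slopes` object; `tidy()` gives one row per predictor.
#' @export
structure_slopes <- function(data, response = "total",
                             predictors = c("cwm_body_mass", "biomass"),
                             transform = c("log", "identity"),
                             n_boot = 1000, seed = 1, standardize = FALSE) {
  transform <- match.arg(transform)
  data <- tibble::as_tibble(data)
  prep <- .prep_hierarchy(data, response, transform)
  y <- prep$y
  eu_of_row <- prep$eu_of_row
  idx <- .boot_ecounits(prep$eu_block, n_boot, seed)
  rows_of_eu <- split(seq_along(y), eu_of_row)

  tab <- purrr::map(predictors, function(p) {
    x <- data[[p]]
    if (is.null(x)) abort(paste0("no such predictor column: ", p))
    if (transform == "log") {
      if (any(x <= 0)) abort(paste0("log transform needs positive ", p))
      x <- log(x)
    }
    if (sd(x) == 0) abort(paste0("zero-variance predictor: ", p))
    if (standardize) x <- as.vector(scale(x))
    obs <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    draws <- vapply(idx, function(eus) {
      r <- unlist(rows_of_eu[eus], use.names = FALSE)
      xr <- x[r]; yr <- y[r]
      sum((xr - mean(xr)) * (yr - mean(yr))) / sum((xr - mean(xr))^2)
    }, numeric(1))
    q <- quantile(draws, c(0.025, 0.975, 0.05, 0.95), names = FALSE)
    tibble::tibble(predictor = p, estimate = obs,
                   lower_95 = q[1], upper_95 = q[2],
                   lower_90 = q[3], upper_90 = q[4])
  }) |> dplyr::bind_rows()
  tab$excludes_zero_95 <- tab$lower_95 > 0 | tab$upper_95 < 0
  tab$excludes_zero_90 <- tab$lower_90 > 0 | tab$upper_90 < 0
  tab$decision <- interval_decision(tab$excludes_zero_95, tab$excludes_zero_90)

  structure(list(slopes = tab, response = response, transform = transform,
                 n_boot = n_boot, seed = seed, n = prep$n),
            class = "structure_slopes")
}

# Validate design columns, transform the response, build the EcoUnit x
# history cell-mean matrix and the EcoUnit/block lookup.
.prep_hierarchy <- function(data, response, transform) {
  data <- tibble::as_tibble(data)
  for (col in c("block", "ecounit", "history")) {
    if (is.null(data[[col]])) abort(paste0("design column missing: ", col))
  }
  y <- data[[response]]
  if (is.null(y)) abort(paste0("no such response column: ", response))
  if (transform == "log") {
    if (any(y <= 0)) abort("log transform requires positive responses")
    y <- log(y)
  }
  hist <- as.character(data$history)
  lev <- levels(data$history) %||% sort(unique(hist))
  eu <- as.character(data$ecounit)
  eus <- unique(eu)
  Y <- tapply(y, list(factor(eu, eus), factor(hist, lev)), mean)
  if (anyNA(Y)) abort("missing treatment cell in the design")
  eu_block <- tapply(as.character(data$block), factor(eu, eus),
                     function(b) b[1])
  list(Y = Y, y = y, eu_of_row = factor(eu, eus),
       eu_block = setNames(as.character(eu_block), eus), n = nrow(data))
}

# List (length n_boot) of resampled EcoUnit index vectors: blocks with
# replacement, then EcoUnits within each sampled block with replacement.
.boot_ecounits <- function(eu_block, n_boot, seed) {
  set.seed(seed)
  blocks <- unique(unname(eu_block))
  eu_by_block <- split(seq_along(eu_block), factor(unname(eu_block), blocks))
  lapply(seq_len(n_boot), function(d) {
    bs <- sample(length(blocks), replace = TRUE)
    unlist(lapply(bs, function(b) {
      pool <- eu_by_block[[b]]
      pool[sample.int(length(pool), replace = TRUE)]
    }), use.names = FALSE)
  })
}

# treatment means per draw from resampled EcoUnit rows of Y
.cell_means <- function(Y, idx) {
  flat <- unlist(idx, use.names = FALSE)
  draw_id <- rep(seq_along(idx), lengths(idx))
  sums <- rowsum(Y[flat, , drop = FALSE], draw_id)
  sums / lengths(idx)
}

#' @export
print.history_contrasts <- function(x, digits = 3, ...) {
  cat("<history_contrasts> response:", x$response,
      "| transform:", x$transform, "| n =", x$n,
      "| bootstrap draws:", x$n_boot, "\n")
  print(as.data.frame(dplyr::mutate(x$contrasts, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, digits)))))
  invisible(x)
}

#' @export
tidy.history_contrasts <- function(x, ...) x$contrasts

#' @export
glance.history_contrasts <- function(x, ...) {
  tibble::tibble(response = x$response, transform = x$transform,
                 n = x$n, n_boot = x$n_boot, seed = x$seed,
                 n_clear = sum(x$contrasts$decision == "clear"))
}

#' @export
print.structure_slopes <- function(x, digits = 3, ...) {
  cat("<structure_slopes> response:", x$response, "| n =", x$n,
      "| bootstrap draws:", x$n_boot, "\n")
  print(as.data.frame(dplyr::mutate(x$slopes, dplyr::across(
    dplyr::where(is.numeric), ~ round(.x, digits)))))
  invisible(x)
}

#' @export
tidy.structure_slopes <- function(x, ...) x$slopes

#' @export
glance.structure_slopes <- function(x, ...) {
  tibble::tibble(response = x$response, transform = x$transform,
                 n = x$n, n_boot = x$n_boot, seed = x$seed)
}
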