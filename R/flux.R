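#' Assimilation efficiencies by resource type
#'
#' Fraction of consumed resource energy that can be metabolized by the
#' consumer, attached to the resource type: 0.906 for animal prey (predation)
#' and microbes (microbivory), 0.545 for plant material (herbivory), 0.158 for
#' detritus (detritivory).
#'
#' @param animal,microbe,plant,detritus efficiencies in (0, 1].
#' @return Named numeric vector over the four resource types.
#' @export
assimilation_efficiencies <- function(animal = 0.906, microbe = 0.906,
                                      plant = 0.545, detritus = 0.158) {
  e <- c(animal = animal, microbe = microbe, plant = plant,
         detritus = detritus)
  if (any(e <= 0 | e > 1)) abort("efficiencies must lie in (0, 1]")
  e
}

#' Solve the steady-state energy fluxes of one food web
#'
#' Under the steady-state assumption, energy lost by every animal node to
#' metabolism and to its consumers is balanced by energy gained from its
#' resources. With W the column-stochastic preference matrix, X_j the
#' population metabolic loss and e-bar_j = sum_i e(type_i) W\[i, j\] the
#' diet-weighted assimilation efficiency of consumer j, total consumption G
#' solves, for every animal node j,
#'
#'   e-bar_j G_j = X_j + sum_k W\[j, k\] G_k
#'
#' Basal nodes have no balance equation. Per-link fluxes are
#' F\[i, j\] = W\[i, j\] G_j (J/h per mesocosm), and aggregates sum F over
#' resource rows by type: predation (animal rows), herbivory (plant),
#' microbivory (microbe), detritivory (detritus); their sum is the total flux,
#' the community's multitrophic functioning.
#'
#' @param W a [build_preference_matrix()] result (or any column-stochastic
#'   matrix with a `node_type` attribute).
#' @param losses named vector of population metabolic losses (J/h) for the
#'   animal nodes; names must match the animal node labels of `W`.
#' @param efficiencies an [assimilation_efficiencies()] vector.
#' @return A `flux_result`: list with `fluxes` (per-link matrix F),
#'   `consumption` (G per animal node), `aggregates` (named vector: total,
#'   predation, herbivory, microbivory, detritivory), `residuals` (relative
#'   balance residual per consumer), `node_type`.
#' @export
#' @examples
#' # a single detritivore feeding on detritus: G = X / 0.158
#' W <- matrix(c(0, 1, 0, 0), 2, 2,
#'             dimnames = list(c("worm", "det"), c("worm", "det")))
#' attr(W, "node_type") <- c(worm = "animal", det = "detritus")
#' solve_fluxes(W, c(worm = 1))
#' @seealso [aggregate_fluxes()], [mesocosm_fluxes()]
solve_fluxes <- function(W, losses, efficiencies = assimilation_efficiencies()) {
  node_type <- attr(W, "node_type")
  if (is.null(node_type)) abort("W must carry a node_type attribute")
  animal <- which(node_type == "animal")
  if (length(animal) == 0) abort("no consumer nodes in web")
  if (is.null(names(losses))) {
    if (length(losses) != length(animal)) {
      abort("losses must be named or match the number of animal nodes")
    }
    names(losses) <- colnames(W)[animal]
  }
  miss <- setdiff(colnames(W)[animal], names(losses))
  if (length(miss) > 0) {
    abort(paste0("no metabolic loss for node(s): ",
                 paste(miss, collapse = ", ")))
  }
  X <- unname(losses[colnames(W)[animal]])
  if (any(X < 0)) abort("metabolic losses must be nonnegative")

  e_node <- unname(efficiencies[node_type]) # efficiency of each resource row
  # diet-weighted consumer efficiency
  e_bar <- as.vector(crossprod(W[, animal, drop = FALSE], e_node))
  csum <- colSums(W[, animal, drop = FALSE])
  if (any(abs(csum - 1) > 1e-8)) {
    abort("consumer columns of W must sum to 1")
  }

  A <- diag(e_bar, nrow = length(animal)) -
    W[animal, animal, drop = FALSE]
  G <- tryCatch(solve(A, X),
                error = function(e) abort("degenerate food web"))
  if (any(G < -1e-10 * max(1, max(abs(G))))) {
    bad <- colnames(W)[animal][G < 0]
    abort(paste0("infeasible steady state: negative consumption for ",
                 paste(bad, collapse = ", ")))
  }
  G <- pmax(G, 0)

  G_all <- numeric(ncol(W))
  G_all[animal] <- G
  F_mat <- W %*% diag(G_all, nrow = length(G_all))
  dimnames(F_mat) <- dimnames(W)

  outflow <- as.vector(W[animal, animal, drop = FALSE] %*% G)
  residual <- abs(e_bar * G - X - outflow) /
    pmax(X, e_bar * G, .Machine$double.eps)

  out <- list(fluxes = F_mat,
              consumption = setNames(G, colnames(W)[animal]),
              aggregates = aggregate_fluxes(F_mat, node_type),
              residuals = setNames(residual, colnames(W)[animal]),
              node_type = node_type,
              efficiencies = efficiencies,
              mesocosm_id = attr(W, "mesocosm_id"))
  class(out) <- "flux_result"
  out
}

#' Aggregate per-link fluxes into trophic-function totals
#'
#' Sums the flux matrix over resource rows by node type: fluxes out of animal
#' nodes are predation, out of plant nodes herbivory, microbe nodes
#' microbivory, detritus nodes detritivory. The total is the grand sum and
#' equals the sum of the four functions exactly.
#'
#' @param fluxes per-link flux matrix (rows = resources, cols = consumers).
#' @param node_type named character vector of node types (taken from the
#'   matrix attribute when absent).
#' @return Named vector: `total`, `predation`, `herbivory`, `microbivory`,
#'   `detritivory`.
#' @export
aggregate_fluxes <- function(fluxes, node_type = attr(fluxes, "node_type")) {
  if (is.null(node_type)) abort("node_type required")
  row_out <- rowSums(fluxes)
  fn <- c(animal = "predation", plant = "herbivory",
          microbe = "microbivory", detritus = "detritivory")
  agg <- vapply(names(fn), function(ty) sum(row_out[node_type == ty]),
                numeric(1))
  names(agg) <- unname(fn)
  c(total = sum(agg), agg)
}

#' @export
print.flux_result <- function(x, digits = 4, ...) {
  cat("<flux_result>", if (!is.null(x$mesocosm_id)) x$mesocosm_id else "",
      "\n")
  print(round(x$aggregates, digits))
  cat("max relative balance residual:",
      format(max(x$residuals), digits = 3), "\n")
  invisible(x)
}

#' @export
tidy.flux_result <- function(x, ...) {
  F_mat <- x$fluxes
  idx <- which(F_mat > 0, arr.ind = TRUE)
  tibble::tibble(
    resource = rownames(F_mat)[idx[, 1]],
    consumer = colnames(F_mat)[idx[, 2]],
    resource_type = unname(x$node_type[idx[, 1]]),
    flux = F_mat[idx]) |>
    dplyr::arrange(.data$consumer, .data$resource)
}

#' @export
glance.flux_result <- function(x, ...) {
  tibble::tibble(
    mesocosm_id = x$mesocosm_id %||% NA_character_,
    total = x$aggregates[["total"]],
    predation = x$aggregates[["predation"]],
    herbivory = x$aggregates[["herbivory"]],
    microbivory = x$aggregates[["microbivory"]],
    detritivory = x$aggregates[["detritivory"]],
    max_residual = max(x$residuals))
}
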