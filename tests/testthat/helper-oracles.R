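# Independent fixed-point oracle for the steady-state flux balance:
# iterate G <- (X + W_aa G) / e_bar until convergence. Uses only the matrix
# W, the losses X and the efficiency table — none of the solver internals.
oracle_fluxes <- function(W, losses, efficiencies = assimilation_efficiencies(),
                          tol = 1e-13, max_iter = 100000) {
  node_type <- attr(W, "node_type")
  animal <- which(node_type == "animal")
  e_node <- efficiencies[node_type]
  e_bar <- as.vector(t(W[, animal, drop = FALSE]) %*% e_node)
  Waa <- W[animal, animal, drop = FALSE]
  X <- losses[colnames(W)[animal]]
  G <- X / e_bar
  for (i in seq_len(max_iter)) {
    G_new <- (X + as.vector(Waa %*% G)) / e_bar
    if (max(abs(G_new - G)) <= tol * max(1, max(abs(G_new)))) {
      return(stats::setNames(G_new, colnames(W)[animal]))
    }
    G <- G_new
  }
  stop("oracle iteration did not converge")
}

# random feasible web of <= n_max nodes built through the package's diet
# machinery; returns W (preference matrix) and X (positive losses)
random_web <- function(n_max = 30) {
  n_animal <- sample(2:(n_max - 3), 1)
  rc <- random_community(n_animal)
  W <- build_preference_matrix(rc$populations, rc$traits)
  X <- stats::setNames(exp(runif(n_animal, -2, 2)), rc$populations$taxon_id)
  list(W = W, X = X)
}
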