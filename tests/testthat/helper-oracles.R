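# Independent oracles and small fixture builders used across the suite.

# Exhaustive simplex grid search for the capacity of a 2- or 3-input
# channel model, step `by` on the probability simplex.
grid_search_capacity <- function(model, by = 0.01) {
  n <- nrow(model$W)
  stopifnot(n %in% c(2, 3))
  best <- -Inf
  if (n == 2) {
    for (p1 in seq(0, 1, by = by)) {
      val <- mutual_information(model, c(p1, 1 - p1))
      if (val > best) best <- val
    }
  } else {
    for (p1 in seq(0, 1, by = by)) {
      for (p2 in seq(0, 1 - p1 + 1e-12, by = by)) {
        val <- mutual_information(model, c(p1, p2, max(1 - p1 - p2, 0)))
        if (val > best) best <- val
      }
    }
  }
  best
}

# Coarse (sigma, nu) grid log-likelihood search, independent of the
# optimizer path: returns the best grid point and its log-likelihood.
grid_search_scaled_t <- function(x, sigma_range, nu_range, n_grid = 50) {
  sig <- exp(seq(log(sigma_range[1]), log(sigma_range[2]),
                 length.out = n_grid))
  nus <- exp(seq(log(nu_range[1]), log(nu_range[2]), length.out = n_grid))
  best <- list(loglik = -Inf)
  for (s in sig) {
    for (v in nus) {
      ll <- sum(stats::dt(x / s, df = v, log = TRUE) - log(s))
      if (ll > best$loglik) best <- list(sigma = s, nu = v, loglik = ll)
    }
  }
  best
}

# A small heterogeneous synthetic population at the default study
# conditions, cheap enough for unit tests.
small_population <- function(n_cells = 12, seed = 101, d = 0.99, ...) {
  simulation_config(n_cells = n_cells, desensitization_d = d, seed = seed,
                    ...)
}

# Single-concentration repeated-stimulation config (the adaptation
# experiment: n pulses at 250 nM).
adaptation_config <- function(n_cells = 25, n_pulses = 20, sigma = 0.1,
                              nu = 5, d = 0.99, seed = 11) {
  des <- stimulus_design(concentrations_nM = 250, n_replicates = n_pulses)
  simulation_config(
    n_cells = n_cells, design = des,
    noise = data.frame(concentration_nM = 250, sigma = sigma, nu = nu),
    desensitization_d = d, seed = seed)
}
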