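# Shared fixture builders; everything is generated in code at test time.

# A random strictly upper triangular 4x4 coupling matrix.
random_triangular <- function(seed, scale = 0.3) {
  set.seed(seed)
  A <- matrix(0, 4, 4)
  A[upper.tri(A)] <- rnorm(6, sd = scale)
  A
}

random_cascade_params <- function(seed, scale = 0.3) {
  set.seed(seed)
  cascade_params(random_triangular(seed, scale), rnorm(4, sd = 0.2))
}

# A random correlation-like PSD covariance.
random_psd_cov <- function(seed, n = 4) {
  set.seed(seed)
  L <- matrix(rnorm(n * n), n)
  S <- crossprod(L) / n
  d <- sqrt(diag(S))
  S / tcrossprod(d)
}

# Small simulated cohort used across tests.
make_trajs <- function(n = 2000, seed = 42, params = table1_params(),
                       reserve = NULL,
                       grid = seq(6, 186, by = 6)) {
  cfg <- cohort_config(n_subjects = n, visit_grid_months = grid, seed = seed)
  x0 <- draw_initial_states(initial_distribution(), n, seed = seed)
  simulate_trajectories(params, x0, cfg, reserve = reserve)
}

interaction_rows <- function(summary) {
  summary[summary$term %in% c("AV45:HippoV", "CSFtau:HippoV"), ]
}
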