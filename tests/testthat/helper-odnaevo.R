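# Compact config factory used across the suite; defaults mirror the
# package defaults except for a shorter horizon.
quick_config <- function(mu = 0.01, sigma = 0.02, eps = 0.5, t_max = 100,
                         seed = NULL, N = 20, N_off = 2, n = 100,
                         variant = "step") {
  sim_config(N = N, N_off = N_off, t_max = t_max,
             kernel = kernel_params(mu = mu, sigma = sigma, n = n),
             fitness = fitness_spec(epsilon = eps, variant = variant),
             seed = seed)
}

# Number of replicates (out of `reps`) whose population adapts.
count_adapted <- function(mu, sigma, eps, reps, seed_base, t_max = 500,
                          threshold = 0.75) {
  sum(vapply(seq_len(reps), function(r) {
    cfg <- quick_config(mu = mu, sigma = sigma, eps = eps, t_max = t_max,
                        seed = seed_base + r)
    !is.na(adaptation_time(run_simulation(cfg, keep_cells = FALSE),
                           threshold))
  }, logical(1)))
}

# Pooled final-generation cell-level h across replicates.
pooled_final_h <- function(mu, sigma, eps, reps, seed_base, t_max = 500) {
  unlist(lapply(seq_len(reps), function(r) {
    cfg <- quick_config(mu = mu, sigma = sigma, eps = eps, t_max = t_max,
                        seed = seed_base + r)
    traj <- run_simulation(cfg)
    traj$cells[[nrow(traj)]]
  }))
}
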