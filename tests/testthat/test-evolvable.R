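test_that("parameter inheritance is exact at delta 0 and bounded otherwise", {
  spec <- param_mutation_spec(delta = 0)
  out <- inherit_parameters(c(0.02, 0.1), c(0, 0.5), spec)
  expect_identical(out$mu, c(0.02, 0.1))
  expect_identical(out$sigma, c(0, 0.5))

  spec2 <- param_mutation_spec(delta = 0.005)
  set.seed(41)
  n_draw <- 1e5
  out2 <- inherit_parameters(rep(0, n_draw), rep(0, n_draw), spec2)
  expect_true(all(out2$mu >= 0) && all(out2$sigma >= 0))
  # mother at the zero bound: clamped N(0, delta) has mean delta/sqrt(2*pi)
  m_th <- 0.005 / sqrt(2 * pi)
  se <- 0.005 * sqrt(0.5 - 1 / (2 * pi)) / sqrt(n_draw)
  expect_lt(abs(mean(out2$mu) - m_th), 4 * se)

  # interior mother: perturbation is zero-mean
  set.seed(42)
  out3 <- inherit_parameters(rep(0.05, n_draw), rep(0.5, n_draw), spec2)
  expect_lt(abs(mean(out3$mu) - 0.05), 4 * 0.005 / sqrt(n_draw))
  expect_lt(abs(mean(out3$sigma) - 0.5), 4 * 0.005 / sqrt(n_draw))
})

test_that("delta 0 evolutionary runs reduce exactly to the frozen base model", {
  cfg <- sim_config(t_max = 100, seed = 42)
  ev <- run_evolutionary_simulation(cfg, env_schedule("switch"),
                                    param_mutation_spec(delta = 0),
                                    keep_cells = FALSE)
  base <- run_simulation(sim_config(t_max = 100,
                                    kernel = kernel_params(mu = 0, sigma = 0),
                                    seed = 42),
                         env_schedule("switch"), keep_cells = FALSE)
  expect_identical(ev$mean_h, base$mean_h)
  expect_identical(ev$mean_fitness, base$mean_fitness)
  expect_true(all(ev$mean_mu == 0) && all(ev$mean_sigma == 0))
})

test_that("pinned mutation rate with delta 0 reduces to the base model", {
  cfg <- sim_config(t_max = 100, kernel = kernel_params(mu = 0.02, sigma = 0),
                    seed = 9)
  f <- run_fixed_mu_evolving_sigma(cfg, env_schedule("switch"),
                                   fixed_mu = 0.02,
                                   pspec = param_mutation_spec(delta = 0),
                                   keep_cells = FALSE)
  base <- run_simulation(cfg, env_schedule("switch"), keep_cells = FALSE)
  expect_identical(f$mean_h, base$mean_h)
  expect_true(all(f$mean_sigma == 0))
})

test_that("zero mutation supply means no adaptation however sigma evolves", {
  cfg <- sim_config(t_max = 150, fitness = fitness_spec(epsilon = 0.2),
                    seed = 43)
  traj <- run_fixed_mu_evolving_sigma(cfg, env_schedule("oscillating",
                                                        tau = 50),
                                      fixed_mu = 0, keep_cells = FALSE)
  expect_true(all(traj$mean_h == 0))
  expect_true(all(traj$mean_mu == 0))
})

test_that("evolved parameters respect their bounds throughout a run", {
  pspec <- param_mutation_spec(delta = 0.02, mu_bounds = c(0, 0.05),
                               sigma_bounds = c(0, 0.3))
  cfg <- sim_config(t_max = 150, fitness = fitness_spec(epsilon = 0.2),
                    seed = 44)
  traj <- run_evolutionary_simulation(cfg, env_schedule("oscillating",
                                                        tau = 50), pspec)
  cellpar <- dplyr::bind_rows(traj$cells)
  expect_true(all(cellpar$mu_i >= 0 & cellpar$mu_i <= 0.05))
  expect_true(all(cellpar$sigma_i >= 0 & cellpar$sigma_i <= 0.3))
})

test_that("nonzero segregation strength emerges under oscillating selection", {
  finals <- vapply(1:10, function(r) {
    cfg <- sim_config(t_max = 150, fitness = fitness_spec(epsilon = 0.2),
                      seed = 4500 + r)
    traj <- run_evolutionary_simulation(cfg,
                                        env_schedule("oscillating", tau = 50),
                                        keep_cells = FALSE)
    traj$mean_sigma[nrow(traj)]
  }, numeric(1))
  expect_true(all(finals > 0))
  expect_gt(mean(finals), 0.01)
})

test_that("fluctuating environments select stronger bottlenecks than static", {
  final_sigma <- function(sched, base, reps = 50) vapply(1:reps, function(r) {
    cfg <- sim_config(fitness = fitness_spec(epsilon = 0.2), seed = base + r)
    traj <- run_evolutionary_simulation(cfg, sched, keep_cells = FALSE)
    traj$mean_sigma[nrow(traj)]
  }, numeric(1))
  fl <- final_sigma(env_schedule("oscillating", tau = 100), 4000)
  st <- final_sigma(env_schedule("switch"), 4100)
  expect_lt(stats::wilcox.test(fl, st, alternative = "greater")$p.value, 0.05)
  expect_gt(mean(fl), mean(st))
})

test_that("adapting populations keep a homoplasmic modal structure", {
  for (s in 7001:7003) {
    cfg <- sim_config(fitness = fitness_spec(epsilon = 0.2), seed = s)
    traj <- run_evolutionary_simulation(cfg,
                                        env_schedule("oscillating", tau = 100))
    h <- traj$cells[[nrow(traj)]]$h
    counts <- tabulate(pmin(floor(h / 0.05), 19) + 1, 20)
    expect_true(which.max(counts) %in% c(1, 20))
  }
})
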