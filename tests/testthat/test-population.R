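test_that("populations initialise homoplasmic wildtype", {
  pop <- init_population(sim_config(N = 20))
  expect_equal(nrow(pop), 20)
  expect_true(all(pop$h == 0))
  expect_equal(mean(pop$h), 0)
  expect_equal(nrow(init_population(sim_config(N = 1))), 1)
  ev <- init_population(sim_config(N = 5), evolvable = TRUE,
                        dysfunctional = TRUE)
  expect_true(all(ev$mu_i == 0) && all(ev$sigma_i == 0) && all(ev$hD == 0))
})

test_that("environment schedules map generations as specified", {
  expect_equal(environment_at(c(0, 1, 499), env_schedule("switch")),
               c("B", "B", "B"))
  expect_equal(environment_at(0:3, env_schedule("static", start_env = "A")),
               rep("A", 4))
  # flips every tau generations from start_env (floor(t/tau) parity)
  osc <- env_schedule("oscillating", tau = 3, start_env = "B")
  expect_equal(environment_at(0:8, osc),
               c("B", "B", "B", "A", "A", "A", "B", "B", "B"))
  expect_equal(environment_at(0, osc), "B")
  expect_error(env_schedule("oscillating"), "tau")
})

test_that("reproduction yields N x N_off independent daughters", {
  cfg <- quick_config(mu = 0, sigma = 0)
  pop <- tibble::tibble(cell = 1:20, h = seq(0, 0.95, by = 0.05))
  pool <- reproduce(pop, cfg)
  expect_equal(nrow(pool), 40)
  expect_equal(pool$mother, rep(1:20, each = 2))
  # zero-rate kernels copy the mother exactly
  expect_equal(pool$h, rep(pop$h, each = 2))
  # homoplasmic mother with no mutation: all daughters identical
  cfg2 <- quick_config(mu = 0, sigma = 0.3)
  pool2 <- reproduce(tibble::tibble(cell = 1, h = 0), cfg2)
  expect_true(all(pool2$h == 0))
})

test_that("roulette selection frequencies track fitness weights", {
  set.seed(11)
  expect_equal(roulette_select(c(0.7), 5), rep(1L, 5))
  # equal weights: uniform; chi-square GOF not rejected at alpha = 0.01
  set.seed(12)
  sel <- roulette_select(rep(0.5, 4), 1e4)
  expect_gt(stats::chisq.test(tabulate(sel, 4))$p.value, 0.01)
  # 0.8 / 0.2 weights: empirical frequency within 4 binomial SEs
  set.seed(13)
  sel2 <- roulette_select(c(0.8, 0.2), 1e4)
  expect_lt(abs(mean(sel2 == 1) - 0.8), 4 * sqrt(0.8 * 0.2 / 1e4))
  expect_error(roulette_select(c(0, 0), 2), "fitness")
})

test_that("a generation step preserves size and is deterministic", {
  cfg <- quick_config(mu = 0, sigma = 0)
  pop <- init_population(cfg)
  set.seed(5)
  nxt <- step_generation(pop, 1, cfg, env_schedule("switch"))
  expect_equal(nrow(nxt), cfg$N)
  expect_true(all(nxt$h == 0))  # frozen homoplasmic population is a fixed point
  cfg2 <- quick_config(mu = 0.05, sigma = 0.1)
  set.seed(6)
  a <- step_generation(pop, 1, cfg2, env_schedule("switch"))
  set.seed(6)
  b <- step_generation(pop, 1, cfg2, env_schedule("switch"))
  expect_identical(a, b)
})

test_that("trajectories have full length, constant N, and reproduce by seed", {
  cfg <- quick_config(mu = 0.02, sigma = 0.05, eps = 0.2, t_max = 60,
                      seed = 21)
  traj <- run_simulation(cfg)
  expect_s3_class(traj, "odna_trajectory")
  expect_equal(nrow(traj), 61)
  expect_equal(traj$generation, 0:60)
  expect_true(all(vapply(traj$cells, length, integer(1)) == cfg$N))
  expect_true(all(traj$mean_h >= 0 & traj$mean_h <= 1))
  traj2 <- run_simulation(cfg)
  expect_equal(tidy(traj), tidy(traj2))
})

test_that("zero mutation leaves the wildtype population frozen", {
  cfg <- quick_config(mu = 0, sigma = 0.3, eps = 0.5, t_max = 120, seed = 31)
  traj <- run_simulation(cfg, keep_cells = FALSE)
  expect_true(all(traj$mean_h == 0))
  expect_false(glance(traj)$adapted)
})

test_that("adaptation time is the first strict threshold crossing", {
  mk <- function(mh) tibble::tibble(generation = seq_along(mh) - 1,
                                    mean_h = mh)
  expect_equal(adaptation_time(mk(c(0, 0.5, 0.8, 0.9))), 2L)
  expect_true(is.na(adaptation_time(mk(rep(0, 10)))))
  # touching the threshold exactly does not count ("exceeds" is strict)
  expect_true(is.na(adaptation_time(mk(c(0, 0.75, 0.75)))))
  expect_equal(adaptation_time(mk(c(0, 0.6, 0.8)), threshold = 0.5), 1L)
})

test_that("selection and mutation push mean h upward without segregation", {
  # env B, no admixture penalty, sigma = 0: both forces point towards 1
  finals <- slopes <- numeric(10)
  for (r in 1:10) {
    cfg <- quick_config(mu = 0.02, sigma = 0, eps = 0, t_max = 150,
                        seed = 6000 + r)
    traj <- run_simulation(cfg, keep_cells = FALSE)
    finals[r] <- traj$mean_h[nrow(traj)]
    slopes[r] <- mean(diff(traj$mean_h))
  }
  expect_gt(mean(slopes), 0)
  # selection carries the population past the mutation-only equilibrium 1/2
  expect_gt(mean(finals), 0.5)
})

test_that("changing the adaptation threshold rescales but preserves order", {
  times <- function(sigma) t(vapply(1:3, function(r) {
    cfg <- quick_config(mu = 0.01, sigma = sigma, eps = 0.5, t_max = 500,
                        seed = 6100 + r)
    traj <- run_simulation(cfg, keep_cells = FALSE)
    c(lo = adaptation_time(traj, 0.5), hi = adaptation_time(traj, 0.75))
  }, c(lo = 0, hi = 0)))
  weak <- times(0.01)
  strong <- times(0.2)
  # earlier threshold is crossed no later, run by run
  expect_true(all(weak[, "lo"] <= weak[, "hi"]))
  expect_true(all(strong[, "lo"] <= strong[, "hi"]))
  # the stronger bottleneck adapts faster under either threshold
  expect_lt(mean(strong[, "lo"]), mean(weak[, "lo"]))
  expect_lt(mean(strong[, "hi"]), mean(weak[, "hi"]))
})
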