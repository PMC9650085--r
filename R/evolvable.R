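## Meta-evolution layer: each cell carries its own organelle mutation rate
## mu_i and segregation strength sigma_i. A daughter's mutant fraction is
## transmitted using her MOTHER'S parameters (the parameters act while the
## mother produces daughters); the daughter then receives her own,
## imperfectly inherited parameter values, which act from the next
## generation onwards.

#' Imperfect inheritance of per-cell kernel parameters
#'
#' Each parameter is independently perturbed by a zero-mean normal variate
#' of standard deviation `delta` and clamped to its admissible interval.
#' With `delta = 0` inheritance is exact and consumes no randomness.
#'
#' @param mu Mother mutation rate(s).
#' @param sigma Mother segregation strength(s), same length as `mu`.
#' @param spec A [param_mutation_spec()] object.
#' @return A list with numeric vectors `mu` and `sigma`.
#' @examples
#' set.seed(1)
#' inherit_parameters(0.05, 0.1, param_mutation_spec(delta = 0.005))
#' @export
inherit_parameters <- function(mu, sigma, spec) {
  d <- spec$delta
  if (d > 0) {
    mu <- mu + rnorm(length(mu), 0, d)
    sigma <- sigma + rnorm(length(sigma), 0, d)
  }
  list(mu = pmin(spec$mu_bounds[2], pmax(spec$mu_bounds[1], mu)),
       sigma = pmin(spec$sigma_bounds[2], pmax(spec$sigma_bounds[1], sigma)))
}

#' Run an evolutionary simulation with heritable kernel parameters
#'
#' As [run_simulation()], but every cell carries its own `(mu_i, sigma_i)`,
#' both starting at zero. Each generation: daughters' mutant fractions are
#' drawn with their mother's parameters; daughters inherit the parameters
#' with perturbation scale `delta` ([inherit_parameters()]); fitness and
#' roulette selection then act on the daughters, so parameter values
#' hitchhike with the adaptive success of the lineages carrying them.
#'
#' With `delta = 0` the parameters are frozen at zero and the run is
#' trajectory-identical (at matched seed) to the base model with
#' `mu = sigma = 0`.
#'
#' @param config A [sim_config()] object (its kernel `mu`/`sigma` are
#'   ignored; `n` and `mut_sd` are used).
#' @param schedule An [env_schedule()] object; default: oscillating with
#'   period 100 starting in B.
#' @param pspec A [param_mutation_spec()] object.
#' @param fixed_mu Optional: pin every cell's mutation rate to this value
#'   for all generations (only `sigma_i` evolves).
#' @param keep_cells Keep per-cell state per generation as a list-column?
#' @return An `odna_trajectory` tibble with additional columns `mean_mu`
#'   and `mean_sigma`; the `cells` list-column (if kept) holds a tibble of
#'   per-cell `h`, `mu_i`, `sigma_i` per generation.
#' @examples
#' traj <- run_evolutionary_simulation(
#'   sim_config(t_max = 50, fitness = fitness_spec(epsilon = 0.2), seed = 1),
#'   env_schedule("oscillating", tau = 25))
#' tail(traj$mean_sigma, 1)
#' @export
run_evolutionary_simulation <- function(config,
                                        schedule = env_schedule("oscillating",
                                                                tau = 100),
                                        pspec = param_mutation_spec(),
                                        fixed_mu = NULL,
                                        keep_cells = TRUE) {
  if (!is.null(fixed_mu)) stopifnot(fixed_mu >= 0)
  if (!is.null(config$seed)) set.seed(config$seed)
  tm <- config$t_max
  N <- config$N
  N_off <- config$N_off
  h <- rep(0, N)
  mu_i <- rep(if (is.null(fixed_mu)) 0 else fixed_mu, N)
  sigma_i <- rep(0, N)
  envs <- environment_at(0:tm, schedule)
  mean_h <- mean_f <- mean_mu <- mean_sg <- numeric(tm + 1)
  cells <- if (keep_cells) vector("list", tm + 1)
  record <- function(i, h, fit, mu_i, sigma_i) {
    mean_h[i] <<- mean(h)
    mean_f[i] <<- mean(fit)
    mean_mu[i] <<- mean(mu_i)
    mean_sg[i] <<- mean(sigma_i)
    if (keep_cells)
      cells[[i]] <<- tibble::tibble(h = h, mu_i = mu_i, sigma_i = sigma_i)
  }
  record(1, h, cell_fitness(h, envs[1], config$fitness), mu_i, sigma_i)
  for (t in seq_len(tm)) {
    hm <- rep(h, each = N_off)
    mu_m <- rep(mu_i, each = N_off)
    sg_m <- rep(sigma_i, each = N_off)
    hd <- segregate_h(mutate_h(hm, config$kernel, mu = mu_m), sg_m)
    if (is.null(fixed_mu)) {
      par_d <- inherit_parameters(mu_m, sg_m, pspec)
      mu_d <- par_d$mu
      sg_d <- par_d$sigma
    } else {
      ## mu pinned: only sigma is perturbed (one draw per daughter)
      mu_d <- mu_m
      sg_d <- sg_m
      if (pspec$delta > 0)
        sg_d <- sg_d + rnorm(length(sg_d), 0, pspec$delta)
      sg_d <- pmin(pspec$sigma_bounds[2], pmax(pspec$sigma_bounds[1], sg_d))
    }
    fit <- cell_fitness(hd, envs[t + 1], config$fitness)
    sel <- roulette_select(fit, N)
    h <- hd[sel]
    mu_i <- mu_d[sel]
    sigma_i <- sg_d[sel]
    record(t + 1, h, fit[sel], mu_i, sigma_i)
  }
  df <- tibble::tibble(generation = 0:tm, environment = envs,
                       mean_h = mean_h, mean_fitness = mean_f,
                       mean_mu = mean_mu, mean_sigma = mean_sg)
  if (keep_cells) df$cells <- cells
  .new_trajectory(df, config, schedule, "evolvable")
}

#' Evolve segregation strength at a fixed mutation rate
#'
#' Convenience wrapper around [run_evolutionary_simulation()] with `mu_i`
#' pinned to `fixed_mu` for all cells and generations; only `sigma_i`
#' evolves. Used to ask how much segregation evolves to compensate for a
#' given mutation-rate supply of variation.
#'
#' @inheritParams run_evolutionary_simulation
#' @param fixed_mu The constant organelle mutation rate (>= 0).
#' @return An `odna_trajectory` tibble (see
#'   [run_evolutionary_simulation()]).
#' @examples
#' traj <- run_fixed_mu_evolving_sigma(
#'   sim_config(t_max = 50, fitness = fitness_spec(epsilon = 0.2), seed = 1),
#'   env_schedule("oscillating", tau = 25), fixed_mu = 0.01)
#' @export
run_fixed_mu_evolving_sigma <- function(config,
                                        schedule = env_schedule("oscillating",
                                                                tau = 100),
                                        fixed_mu,
                                        pspec = param_mutation_spec(),
                                        keep_cells = TRUE) {
  run_evolutionary_simulation(config, schedule, pspec, fixed_mu = fixed_mu,
                              keep_cells = keep_cells)
}
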