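#' Heteroplasmy transition-kernel parameters
#'
#' Bundles the per-generation kernel parameters: the per-molecule organelle
#' mutation rate `mu`, the segregation ("bottleneck") strength `sigma`, and
#' the oDNA copy number per cell `n`. `sigma` is parameterised so that the
#' variance added to a daughter's mutant fraction in one generation is
#' `sigma * h * (1 - h)`; it is therefore comparable to the normalised
#' heteroplasmy variance V'(h) reported in transmission studies, and to the
#' inverse of an effective bottleneck size.
#'
#' @param mu Per-molecule mutation rate per generation (>= 0). Default 0.01.
#' @param sigma Segregation strength per generation (>= 0). Default 0.02.
#' @param n oDNA copy number per cell (positive integer). Default 100.
#' @param mut_sd Form of the mutation-kernel spread: `"sqrt"` (default) uses
#'   standard deviation `sqrt(mu / n)`, the binomial copy-number result for
#'   `n` molecules each switching type with probability `mu`; `"linear"`
#'   uses `mu / n` literally as the standard deviation.
#' @return A list of class `kernel_params`.
#' @examples
#' kernel_params(mu = 0.005, sigma = 0.02)
#' @export
kernel_params <- function(mu = 0.01, sigma = 0.02, n = 100,
                          mut_sd = c("sqrt", "linear")) {
  mut_sd <- match.arg(mut_sd)
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0,
            is.numeric(sigma), length(sigma) == 1, sigma >= 0,
            is.numeric(n), length(n) == 1, n >= 1)
  structure(list(mu = mu, sigma = sigma, n = as.integer(n), mut_sd = mut_sd),
            class = "kernel_params")
}

#' Environment-dependent fitness specification
#'
#' Fitness is sigmoidal, `1 / (1 + exp(-2 * (f_E(h) + f_eps(h))))`, where the
#' performance part `f_E(h)` is `-h` in environment A (wildtype favoured) and
#' `+h` in environment B (mutant favoured), and `f_eps` is an admixture
#' penalty of scale `epsilon` applied to heteroplasmic cells. Three penalty
#' shapes are supported:
#' * `"step"`: 0 at homoplasmy (h = 0 or 1), `-epsilon` otherwise;
#' * `"smooth"`: `4 * epsilon * (h - 1/2)^2 - epsilon`, a smooth valley;
#' * `"threshold"`: 0 for `h <= threshold_h`, `-epsilon` above it, modelling
#'   threshold-effect phenotypes where cost only appears beyond a mutant
#'   load. By default homoplasmic mutant cells (h = 1) are exempt, matching
#'   the step variant; set `exempt_mutant_homoplasmy = FALSE` to penalise
#'   them too.
#'
#' @param epsilon Admixture penalty scale (>= 0). Default 0.5.
#' @param variant One of `"step"`, `"smooth"`, `"threshold"`.
#' @param threshold_h Mutant-fraction threshold for the threshold variant,
#'   in (0, 1). Default 0.2.
#' @param exempt_mutant_homoplasmy Should `h = 1` be unpenalised under the
#'   threshold variant? Default `TRUE`.
#' @return A list of class `fitness_spec`.
#' @examples
#' fitness_spec(epsilon = 0.8)
#' fitness_spec(epsilon = 0.3, variant = "smooth")
#' @export
fitness_spec <- function(epsilon = 0.5,
                         variant = c("step", "smooth", "threshold"),
                         threshold_h = 0.2,
                         exempt_mutant_homoplasmy = TRUE) {
  variant <- match.arg(variant)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1, epsilon >= 0)
  if (variant == "threshold") {
    stopifnot(is.numeric(threshold_h), length(threshold_h) == 1,
              threshold_h > 0, threshold_h < 1)
  }
  structure(list(epsilon = epsilon, variant = variant,
                 threshold_h = threshold_h,
                 exempt_mutant_homoplasmy = isTRUE(exempt_mutant_homoplasmy)),
            class = "fitness_spec")
}

#' Environment schedule
#'
#' Maps a generation index to one of the two environments A (wildtype
#' favoured) and B (mutant favoured).
#'
#' * `"switch"`: the population is A-adapted at initialisation and
#'   environment B is imposed from generation 0 onwards (a single
#'   environmental change at t = 0, then constant).
#' * `"static"`: `start_env` for every generation.
#' * `"oscillating"`: the environment flips every `tau` generations,
#'   starting from `start_env`; generation `t` sees `start_env` when
#'   `floor(t / tau)` is even. `start_env` defaults to B so that t = 0
#'   imposes the novel environment, consistent with the switch schedule.
#'
#' @param mode One of `"switch"`, `"static"`, `"oscillating"`.
#' @param tau Oscillation period in generations (>= 1); required for the
#'   oscillating mode. `tau = Inf` degenerates to the switch schedule.
#' @param start_env `"A"` or `"B"`. Defaults: switch/oscillating `"B"`,
#'   static `"A"`.
#' @return A list of class `env_schedule`.
#' @examples
#' env_schedule("oscillating", tau = 100)
#' environment_at(0:5, env_schedule("oscillating", tau = 2))
#' @export
env_schedule <- function(mode = c("switch", "static", "oscillating"),
                         tau = NULL, start_env = NULL) {
  mode <- match.arg(mode)
  if (is.null(start_env)) start_env <- if (mode == "static") "A" else "B"
  stopifnot(start_env %in% c("A", "B"))
  if (mode == "oscillating") {
    if (is.null(tau) || !is.numeric(tau) || length(tau) != 1 || tau < 1)
      stop("oscillating schedule requires a period `tau` >= 1", call. = FALSE)
  }
  structure(list(mode = mode, tau = tau, start_env = start_env),
            class = "env_schedule")
}

#' Simulation configuration
#'
#' Demography plus kernel and fitness specifications for a population run.
#' Defaults are the study conditions used throughout: `N = 20` mother cells,
#' `N_off = 2` daughters per mother, `n = 100` oDNA copies per cell and
#' `t_max = 500` generations.
#'
#' @param N Number of mother cells per generation (>= 1).
#' @param N_off Daughters per mother (>= 1).
#' @param t_max Number of generations to simulate (>= 1).
#' @param kernel A [kernel_params()] object.
#' @param fitness A [fitness_spec()] object.
#' @param seed Optional integer seed; if non-`NULL`, run functions call
#'   `set.seed(seed)` before drawing anything.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(kernel = kernel_params(mu = 0.005, sigma = 0.02),
#'                   fitness = fitness_spec(epsilon = 0.8), seed = 1)
#' @export
sim_config <- function(N = 20, N_off = 2, t_max = 500,
                       kernel = kernel_params(),
                       fitness = fitness_spec(),
                       seed = NULL) {
  stopifnot(N >= 1, N_off >= 1, t_max >= 1,
            inherits(kernel, "kernel_params"),
            inherits(fitness, "fitness_spec"))
  if (!is.null(seed)) stopifnot(is.numeric(seed), length(seed) == 1)
  structure(list(N = as.integer(N), N_off = as.integer(N_off),
                 t_max = as.integer(t_max), kernel = kernel,
                 fitness = fitness,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

#' Heritable-parameter mutation specification
#'
#' Controls the evolvable layer, in which each cell carries its own mutation
#' rate `mu_i` and segregation strength `sigma_i`. Both are inherited from
#' mother to daughter with imperfect transmission: each is independently
#' perturbed by a zero-mean normal variate of standard deviation `delta`
#' (the parameter-mutation rate, distinct from the organelle mutation rate)
#' and clamped to its admissible range.
#'
#' @param delta Standard deviation of the per-daughter parameter
#'   perturbation (>= 0). Default 0.005.
#' @param mu_bounds Closed admissible interval for `mu_i`; lower limit 0.
#'   Default `c(0, 0.2)`.
#' @param sigma_bounds Closed admissible interval for `sigma_i`; lower
#'   limit 0. `sigma` is a normalised-variance-like quantity, so the default
#'   ceiling is 1: `c(0, 1)`.
#' @return A list of class `param_mutation_spec`.
#' @examples
#' param_mutation_spec(delta = 0.005)
#' @export
param_mutation_spec <- function(delta = 0.005,
                                mu_bounds = c(0, 0.2),
                                sigma_bounds = c(0, 1)) {
  stopifnot(is.numeric(delta), length(delta) == 1, delta >= 0,
            length(mu_bounds) == 2, mu_bounds[1] == 0,
            mu_bounds[2] > mu_bounds[1],
            length(sigma_bounds) == 2, sigma_bounds[1] == 0,
            sigma_bounds[2] > sigma_bounds[1])
  structure(list(delta = delta, mu_bounds = as.numeric(mu_bounds),
                 sigma_bounds = as.numeric(sigma_bounds)),
            class = "param_mutation_spec")
}

#' Dysfunctional-oDNA mutation rates
#'
#' Parameters of the three-type extension (wildtype, mutant, dysfunctional):
#' the functional-type switching rate is the base kernel's `mu`, and
#' off-target mutation converts functional molecules to the dysfunctional
#' class at rate `mu_D = alpha * mu`. `alpha` is the relative propensity of
#' mutations to switch between functional types versus inducing
#' dysfunctionality.
#'
#' @param mu Functional-type switching rate (>= 0).
#' @param alpha Ratio `mu_D / mu` (>= 0).
#' @return A list of class `dys_rates` with fields `mu`, `alpha`, `mu_D`.
#' @examples
#' dys_rates(mu = 0.01, alpha = 1)
#' @export
dys_rates <- function(mu = 0.01, alpha = 0) {
  stopifnot(is.numeric(mu), length(mu) == 1, mu >= 0,
            is.numeric(alpha), length(alpha) == 1, alpha >= 0)
  structure(list(mu = mu, alpha = alpha, mu_D = alpha * mu),
            class = "dys_rates")
}
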