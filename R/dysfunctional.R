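## Three-type extension: wildtype w, mutant m, dysfunctional d. The cell
## state is (h, hD) with h = m / (w + m) the mutant proportion among
## functional molecules and hD = d / (w + m + d) the dysfunctional load.
## Off-target mutation converts functional molecules (either type) to the
## dysfunctional class at rate mu_D = alpha * mu; because conversion samples
## wildtype and mutant proportionally, the marginal kernel for h is the
## unchanged two-type mutation kernel. Both coordinates are moment-matched
## by the same binomial logic as the base kernels: hD gains mean increment
## mu_D * (1 - hD) with spread sqrt(mu_D * (1 - hD) / n) (vanishing at
## hD = 1, so total dysfunction is absorbing), and segregation perturbs each
## coordinate independently with variance sigma * x * (1 - x).

#' Three-type mutation kernel
#'
#' Updates `(h, hD)` for one generation of mutation: `h` follows the base
#' two-type kernel ([mutate_h()]) with rate `mu`, and `hD` drifts upward by
#' one-way functional-to-dysfunctional conversion at rate `mu_D = alpha *
#' mu`, with normal spread matched to the binomial conversion variance.
#' With `alpha = 0` the `hD` coordinate is untouched and consumes no
#' randomness, reducing exactly to the base model. Draw order per daughter:
#' `h` first, then `hD`.
#'
#' @param h Mutant fraction(s) among functional molecules, in [0, 1].
#' @param hD Dysfunctional proportion(s), in [0, 1].
#' @param rates A [dys_rates()] object.
#' @param params A [kernel_params()] object supplying `n` and `mut_sd`
#'   (its `mu` is ignored in favour of `rates$mu`).
#' @param clamp Clamp results to [0, 1]? Default `TRUE`; `FALSE` exposes
#'   raw kernel variates for moment diagnostics.
#' @return A list with numeric vectors `h` and `hD`.
#' @examples
#' set.seed(1)
#' mutate_tri(0.3, 0.1, dys_rates(mu = 0.01, alpha = 1), kernel_params())
#' @export
mutate_tri <- function(h, hD, rates, params, clamp = TRUE) {
  h2 <- mutate_h(h, params, mu = rates$mu, clamp = clamp)
  muD <- rates$mu_D
  hD2 <- .draw_normal(hD + muD * (1 - hD),
                      .mut_sd(muD * (1 - hD), params$n, params$mut_sd))
  if (clamp) hD2 <- clamp01(hD2)
  list(h = h2, hD = hD2)
}

#' Three-type segregation kernel
#'
#' Applies independent segregation perturbations of variance
#' `sigma * x * (1 - x)` to each coordinate of `(h, hD)`, clamped to
#' [0, 1]. Homoplasmic coordinates (exactly 0 or 1) are fixed points. Draw
#' order per daughter: `h` first, then `hD`.
#'
#' @inheritParams mutate_tri
#' @param sigma Segregation strength (>= 0).
#' @return A list with numeric vectors `h` and `hD`.
#' @examples
#' set.seed(1)
#' segregate_tri(0.5, 0.5, 0.05)
#' @export
segregate_tri <- function(h, hD, sigma, clamp = TRUE) {
  list(h = segregate_h(h, sigma, clamp = clamp),
       hD = segregate_h(hD, sigma, clamp = clamp))
}

#' Run a three-type simulation with dysfunctional oDNA
#'
#' As [run_simulation()], but each cell carries `(h, hD)` updated by the
#' three-type kernels and fitness is [cell_fitness_dys()]. Cells whose
#' dysfunctional load reaches exactly 1 retain no functional oDNA and are
#' non-viable: they are assigned fitness 0, so selection never picks them
#' while any viable daughter exists. If the whole daughter pool is
#' non-viable the population is extinct and the run stops early (the
#' trajectory is truncated and flagged).
#'
#' @param config A [sim_config()] object; `config$kernel$mu` is the
#'   functional-type switching rate and `config$kernel$sigma` the
#'   segregation strength.
#' @param schedule An [env_schedule()] object.
#' @param alpha Ratio of the off-target (dysfunction-inducing) to the
#'   functional-type switching mutation rate, `mu_D / mu` (>= 0).
#' @param keep_cells Keep per-cell state per generation as a list-column?
#' @return An `odna_trajectory` tibble with additional columns `mean_hD`
#'   and `viable_fraction`; attribute `extinct` is `TRUE` if the run ended
#'   by whole-pool non-viability. The `cells` list-column (if kept) holds a
#'   tibble of per-cell `h`, `hD` per generation.
#' @examples
#' traj <- run_tri_simulation(sim_config(t_max = 50, seed = 1), alpha = 1)
#' tail(traj$mean_hD, 1)
#' @export
run_tri_simulation <- function(config, schedule = env_schedule("switch"),
                               alpha = 0, keep_cells = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  rates <- dys_rates(mu = config$kernel$mu, alpha = alpha)
  tm <- config$t_max
  N <- config$N
  h <- rep(0, N)
  hD <- rep(0, N)
  envs <- environment_at(0:tm, schedule)
  mean_h <- mean_f <- mean_hD <- viable_frac <- numeric(tm + 1)
  cells <- if (keep_cells) vector("list", tm + 1)
  extinct <- FALSE
  record <- function(i, h, hD, fit) {
    mean_h[i] <<- mean(h)
    mean_f[i] <<- mean(fit)
    mean_hD[i] <<- mean(hD)
    viable_frac[i] <<- mean(hD < 1)
    if (keep_cells) cells[[i]] <<- tibble::tibble(h = h, hD = hD)
  }
  fit0 <- ifelse(hD < 1, cell_fitness_dys(h, hD, envs[1], config$fitness), 0)
  record(1, h, hD, fit0)
  last <- tm
  for (t in seq_len(tm)) {
    hm <- rep(h, each = config$N_off)
    hDm <- rep(hD, each = config$N_off)
    st <- mutate_tri(hm, hDm, rates, config$kernel)
    st <- segregate_tri(st$h, st$hD, config$kernel$sigma)
    viable <- st$hD < 1
    if (!any(viable)) {
      extinct <- TRUE
      last <- t - 1
      break
    }
    fit <- ifelse(viable,
                  cell_fitness_dys(st$h, st$hD, envs[t + 1], config$fitness),
                  0)
    sel <- roulette_select(fit, N)
    h <- st$h[sel]
    hD <- st$hD[sel]
    record(t + 1, h, hD, fit[sel])
  }
  keep <- seq_len(last + 1)
  df <- tibble::tibble(generation = (0:tm)[keep], environment = envs[keep],
                       mean_h = mean_h[keep], mean_fitness = mean_f[keep],
                       mean_hD = mean_hD[keep],
                       viable_fraction = viable_frac[keep])
  if (keep_cells) df$cells <- cells[keep]
  .new_trajectory(df, config, schedule, "dysfunctional", extinct = extinct)
}
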