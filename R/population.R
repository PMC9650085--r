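## Population layer: N mothers each produce N_off daughters through the
## transmission kernel; daughters are assigned fitness in the current
## environment and the next generation of N cells is drawn by roulette-wheel
## selection (with replacement, probability proportional to fitness).
## Mothers die each generation; selection acts on daughters only.

#' Initialise a population
#'
#' All cells start homoplasmic wildtype (`h = 0`), the variant optimal for
#' environment A; with the evolvable layer, per-cell parameters start at
#' zero; with the dysfunctional extension, `hD = 0`.
#'
#' @param config A [sim_config()] object.
#' @param evolvable Add zero-initialised `mu_i`, `sigma_i` columns?
#' @param dysfunctional Add a zero-initialised `hD` column?
#' @return A tibble with one row per cell and column `h` (plus optional
#'   `mu_i`, `sigma_i`, `hD`).
#' @examples
#' init_population(sim_config(N = 5))
#' @export
init_population <- function(config, evolvable = FALSE, dysfunctional = FALSE) {
  out <- tibble::tibble(cell = seq_len(config$N), h = 0)
  if (dysfunctional) out$hD <- 0
  if (evolvable) {
    out$mu_i <- 0
    out$sigma_i <- 0
  }
  out
}

#' Environment at a generation
#'
#' Applies an [env_schedule()] to generation indices. Vectorised over `t`.
#'
#' @param t Generation index (>= 0), vectorised.
#' @param schedule An [env_schedule()] object.
#' @return Character vector of `"A"` / `"B"`.
#' @examples
#' environment_at(0:5, env_schedule("oscillating", tau = 3))
#' @export
environment_at <- function(t, schedule) {
  stopifnot(all(t >= 0))
  other <- function(e) ifelse(e == "A", "B", "A")
  switch(schedule$mode,
    static = rep(schedule$start_env, length(t)),
    switch = rep("B", length(t)),
    oscillating = {
      if (is.infinite(schedule$tau)) rep(schedule$start_env, length(t))
      else ifelse(floor(t / schedule$tau) %% 2 == 0,
                  schedule$start_env, other(schedule$start_env))
    }
  )
}

#' Produce the daughter pool
#'
#' Each of the N mothers gives rise to `N_off` daughters; each daughter's
#' mutant fraction is an independent [transmit_h()] draw from its mother's.
#' Daughters are ordered mother-by-mother.
#'
#' @param pop Population tibble (column `h`), as from [init_population()].
#' @param config A [sim_config()] object.
#' @return A tibble of `N * N_off` daughters with columns `mother` and `h`.
#' @examples
#' set.seed(1)
#' reproduce(init_population(sim_config(N = 3)), sim_config(N = 3))
#' @export
reproduce <- function(pop, config) {
  hm <- rep(pop$h, each = config$N_off)
  tibble::tibble(mother = rep(seq_len(nrow(pop)), each = config$N_off),
                 h = transmit_h(hm, config$kernel))
}

#' Roulette-wheel selection
#'
#' Draws `N` indices with replacement from `seq_along(fit)` with probability
#' proportional to fitness. Sigmoidal fitness is strictly positive, so the
#' wheel is always well defined in the base model.
#'
#' @param fit Numeric vector of fitness values (non-negative, not all zero).
#' @param N Number of cells to select.
#' @return Integer vector of selected indices, length `N`.
#' @examples
#' set.seed(1)
#' roulette_select(c(0.8, 0.2), 10)
#' @export
roulette_select <- function(fit, N) {
  if (all(fit <= 0)) stop("no cell has positive fitness", call. = FALSE)
  sample.int(length(fit), N, replace = TRUE, prob = fit)
}

#' Advance the population one generation
#'
#' Reproduce, assign fitness in the environment of generation `t`, then
#' select N daughters by roulette wheel. There is no selection among
#' mothers before reproduction.
#'
#' @param pop Population tibble (column `h`).
#' @param t Generation index being created (>= 1).
#' @param config A [sim_config()] object.
#' @param schedule An [env_schedule()] object.
#' @return The next-generation population tibble of `N` rows.
#' @examples
#' set.seed(1)
#' step_generation(init_population(sim_config(N = 5)), 1,
#'                 sim_config(N = 5), env_schedule("switch"))
#' @export
step_generation <- function(pop, t, config, schedule) {
  env <- environment_at(t, schedule)
  pool <- reproduce(pop, config)
  fit <- cell_fitness(pool$h, env, config$fitness)
  sel <- roulette_select(fit, config$N)
  tibble::tibble(cell = seq_len(config$N), h = pool$h[sel])
}

.new_trajectory <- function(df, config, schedule, type, extinct = FALSE) {
  structure(df,
            class = c("odna_trajectory", class(tibble::tibble())),
            config = config, schedule = schedule, sim_type = type,
            extinct = extinct)
}

#' Run a base-model simulation
#'
#' Tracks a population of `N` cells over `t_max` generations under a given
#' environment schedule, starting from homoplasmic wildtype (`h = 0` for
#' every cell). The returned trajectory has one row per generation,
#' including the initial state (so `t_max + 1` rows).
#'
#' @param config A [sim_config()] object.
#' @param schedule An [env_schedule()] object; default: switch to
#'   environment B at t = 0.
#' @param keep_cells Keep the full per-cell `h` vector per generation as a
#'   list-column `cells`? Default `TRUE` (needed for distribution time
#'   series).
#' @return A tibble of class `odna_trajectory` with columns `generation`,
#'   `environment`, `mean_h`, `mean_fitness` (and `cells` if requested).
#' @examples
#' traj <- run_simulation(sim_config(t_max = 50, seed = 1))
#' adaptation_time(traj)
#' @export
run_simulation <- function(config, schedule = env_schedule("switch"),
                           keep_cells = TRUE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  tm <- config$t_max
  h <- rep(0, config$N)
  envs <- environment_at(0:tm, schedule)
  mean_h <- mean_f <- numeric(tm + 1)
  cells <- if (keep_cells) vector("list", tm + 1)
  record <- function(i, h, fit) {
    mean_h[i] <<- mean(h)
    mean_f[i] <<- mean(fit)
    if (keep_cells) cells[[i]] <<- h
  }
  record(1, h, cell_fitness(h, envs[1], config$fitness))
  for (t in seq_len(tm)) {
    hm <- rep(h, each = config$N_off)
    hd <- transmit_h(hm, config$kernel)
    fit <- cell_fitness(hd, envs[t + 1], config$fitness)
    sel <- roulette_select(fit, config$N)
    h <- hd[sel]
    record(t + 1, h, fit[sel])
  }
  df <- tibble::tibble(generation = 0:tm, environment = envs,
                       mean_h = mean_h, mean_fitness = mean_f)
  if (keep_cells) df$cells <- cells
  .new_trajectory(df, config, schedule, "base")
}

#' First generation at which the population adapts
#'
#' Adaptation to the mutant oDNA type is the first generation at which the
#' population mean mutant fraction strictly exceeds the threshold (75% by
#' default). Changing the threshold rescales adaptation times but preserves
#' their ordering across parameter settings.
#'
#' @param traj A trajectory tibble with columns `generation` and `mean_h`.
#' @param threshold Adaptation threshold, default 0.75; crossing is strict
#'   (`mean_h > threshold`).
#' @return The first qualifying generation index, or `NA_integer_` if the
#'   population never adapts within the trajectory.
#' @examples
#' adaptation_time(tibble::tibble(generation = 0:3,
#'                                mean_h = c(0, 0.5, 0.8, 0.9)))
#' @export
adaptation_time <- function(traj, threshold = 0.75) {
  hit <- which(traj$mean_h > threshold)
  if (length(hit) == 0) NA_integer_ else as.integer(traj$generation[hit[1]])
}
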