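## Experiment harness: two-parameter grid sweeps with replicate averaging,
## heteroplasmy distribution time series, and evolved-parameter surfaces.
## Every replicate of every pixel gets its own documented derived seed, so
## pixels are independent and individually reproducible.

#' Derive a per-replicate pixel seed
#'
#' Deterministic seed for replicate `r` of grid pixel `(i, j)` under root
#' seed `root`: `(root + i * 1299709 + j * 7907 + r * 104729) mod
#' (2^31 - 1)` (three distinct primes keep pixels and replicates on
#' separated streams). Re-running a single simulation with this seed
#' reproduces the corresponding sweep entry exactly.
#'
#' @param root Root seed (integer).
#' @param i,j Pixel indices (1-based; vectorised).
#' @param r Replicate index (1-based; vectorised).
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @examples
#' pixel_seed(1, 2, 3, 4)
#' @export
pixel_seed <- function(root, i, j, r) {
  as.integer((as.numeric(root) + as.numeric(i) * 1299709 +
                as.numeric(j) * 7907 + as.numeric(r) * 104729) %% 2147483647)
}

#' Specify a parameter sweep
#'
#' Two named axes, each a vector of values for a recognised parameter name:
#' `mu`, `sigma`, `n`, `epsilon`, `threshold_h`, `tau`, `N`, `N_off`,
#' `t_max`, `delta`, `alpha`, `fixed_mu`. `fixed` supplies constant
#' overrides with the same names. For evolutionary sweeps a `tau` axis may
#' include `Inf`, meaning a static (switch-then-constant) environment.
#'
#' @param axes Named list of exactly two numeric vectors.
#' @param fixed Named list of constant parameter overrides.
#' @param replicates Simulations per pixel. Defaults: 10 for adaptation
#'   sweeps, 100 for evolutionary sweeps (set explicitly to scale down).
#' @param seed Root seed for [pixel_seed()] derivation.
#' @param config Base [sim_config()] to modify.
#' @param schedule Base [env_schedule()] to modify.
#' @return A list of class `sweep_spec`.
#' @examples
#' sweep_spec(axes = list(mu = c(0, 0.01), epsilon = c(0.2, 0.8)),
#'            replicates = 2, seed = 1)
#' @export
sweep_spec <- function(axes, fixed = list(), replicates = 10, seed = 1,
                       config = sim_config(),
                       schedule = env_schedule("switch")) {
  stopifnot(is.list(axes), length(axes) == 2, !is.null(names(axes)),
            all(nzchar(names(axes))), replicates >= 1)
  ok <- c("mu", "sigma", "n", "epsilon", "threshold_h", "tau", "N", "N_off",
          "t_max", "delta", "alpha", "fixed_mu")
  bad <- setdiff(c(names(axes), names(fixed)), ok)
  if (length(bad))
    stop("unknown sweep parameter(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(axes = axes, fixed = fixed,
                 replicates = as.integer(replicates),
                 seed = as.integer(seed), config = config,
                 schedule = schedule),
            class = "sweep_spec")
}

## Apply named parameter values to (config, schedule, pspec, alpha).
.apply_params <- function(spec, params) {
  config <- spec$config
  schedule <- spec$schedule
  pspec <- spec$pspec %||% param_mutation_spec()
  alpha <- 0
  fixed_mu <- NULL
  for (nm in names(params)) {
    v <- params[[nm]]
    switch(nm,
      mu = config$kernel$mu <- v,
      sigma = config$kernel$sigma <- v,
      n = config$kernel$n <- as.integer(v),
      epsilon = config$fitness$epsilon <- v,
      threshold_h = config$fitness$threshold_h <- v,
      tau = {
        if (is.infinite(v)) schedule <- env_schedule("switch")
        else schedule <- env_schedule("oscillating", tau = v,
                                      start_env = "B")
      },
      N = config$N <- as.integer(v),
      N_off = config$N_off <- as.integer(v),
      t_max = config$t_max <- as.integer(v),
      delta = pspec$delta <- v,
      alpha = alpha <- v,
      fixed_mu = fixed_mu <- v
    )
  }
  list(config = config, schedule = schedule, pspec = pspec, alpha = alpha,
       fixed_mu = fixed_mu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.new_sweep <- function(df, spec, type) {
  structure(df, class = c("odna_sweep", class(tibble::tibble())),
            spec = spec, sweep_type = type)
}

.sweep_grid <- function(spec) {
  ax <- spec$axes
  tidyr::expand_grid(i = seq_along(ax[[1]]), j = seq_along(ax[[2]])) |>
    dplyr::mutate("{names(ax)[1]}" := ax[[1]][.data$i],
                  "{names(ax)[2]}" := ax[[2]][.data$j])
}

#' Adaptation-time sweep over a parameter grid
#'
#' Runs `replicates` base-model simulations per pixel of a two-parameter
#' grid (switch-to-B schedule unless overridden) and aggregates the
#' adaptation time and the final population mean mutant fraction.
#' Replicates that never adapt are censored at `t_max + 1` generations when
#' averaging, and counted in `n_censored` so censored pixels are
#' identifiable.
#'
#' @param spec A [sweep_spec()] object.
#' @param summarise If `FALSE`, return one row per replicate (columns
#'   `adaptation_time` with `NA` for non-adapted, `final_h`, `seed`)
#'   instead of per-pixel means.
#' @return A tibble of class `odna_sweep`: axis columns plus
#'   `mean_adaptation_time` (censored mean), `n_censored`, `n_adapted`,
#'   `mean_final_h`, `replicates`.
#' @examples
#' sw <- sweep_adaptation(sweep_spec(
#'   axes = list(mu = c(0, 0.05), sigma = c(0, 0.02)),
#'   fixed = list(epsilon = 0.2, t_max = 100), replicates = 2, seed = 1))
#' @export
sweep_adaptation <- function(spec, summarise = TRUE) {
  grid <- .sweep_grid(spec)
  rows <- purrr::pmap(grid, function(i, j, ...) {
    vals <- c(list(...), spec$fixed)
    ap <- .apply_params(spec, vals)
    purrr::map(seq_len(spec$replicates), function(r) {
      cfg <- ap$config
      cfg$seed <- pixel_seed(spec$seed, i, j, r)
      traj <- run_simulation(cfg, ap$schedule, keep_cells = FALSE)
      tibble::tibble(i = i, j = j, replicate = r, seed = cfg$seed,
                     adaptation_time = adaptation_time(traj),
                     final_h = traj$mean_h[nrow(traj)],
                     t_max = cfg$t_max)
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows <- dplyr::left_join(grid, rows, by = c("i", "j"))
  if (!summarise) return(.new_sweep(rows, spec, "adaptation_replicates"))
  out <- rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("i", "j",
                                                  names(spec$axes))))) |>
    dplyr::summarise(
      mean_adaptation_time = mean(
        ifelse(is.na(.data$adaptation_time), .data$t_max + 1,
               .data$adaptation_time)),
      n_censored = sum(is.na(.data$adaptation_time)),
      n_adapted = sum(!is.na(.data$adaptation_time)),
      mean_final_h = mean(.data$final_h),
      replicates = dplyr::n(),
      .groups = "drop")
  .new_sweep(out, spec, "adaptation")
}

#' Evolved-parameter sweep (epsilon x tau surfaces)
#'
#' Runs `replicates` evolutionary simulations per pixel (per-cell `mu_i`,
#' `sigma_i` starting at zero) and averages the final-generation population
#' means of the evolved mutation rate and segregation strength. A `tau`
#' axis value of `Inf` denotes the static (switch-then-constant)
#' environment.
#'
#' @param spec A [sweep_spec()] object; `spec$fixed$delta` sets the
#'   parameter-mutation rate (default 0.005).
#' @param pspec Base [param_mutation_spec()] (bounds etc.).
#' @param summarise If `FALSE`, return one row per replicate with the
#'   final `final_mu`, `final_sigma`, `final_h` (the per-pixel scatter of
#'   evolved parameter combinations) instead of per-pixel means.
#' @return A tibble of class `odna_sweep`: axis columns plus
#'   `mean_final_mu`, `mean_final_sigma`, `mean_final_h`, `replicates`.
#' @examples
#' sw <- sweep_evolutionary(sweep_spec(
#'   axes = list(epsilon = c(0.2), tau = c(25, Inf)),
#'   fixed = list(t_max = 50), replicates = 2, seed = 1))
#' @export
sweep_evolutionary <- function(spec, pspec = param_mutation_spec(),
                               summarise = TRUE) {
  spec$pspec <- pspec
  grid <- .sweep_grid(spec)
  rows <- purrr::pmap(grid, function(i, j, ...) {
    vals <- c(list(...), spec$fixed)
    ap <- .apply_params(spec, vals)
    purrr::map(seq_len(spec$replicates), function(r) {
      cfg <- ap$config
      cfg$seed <- pixel_seed(spec$seed, i, j, r)
      traj <- run_evolutionary_simulation(cfg, ap$schedule, ap$pspec,
                                          fixed_mu = ap$fixed_mu,
                                          keep_cells = FALSE)
      last <- nrow(traj)
      tibble::tibble(i = i, j = j, replicate = r, seed = cfg$seed,
                     final_mu = traj$mean_mu[last],
                     final_sigma = traj$mean_sigma[last],
                     final_h = traj$mean_h[last])
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()
  rows <- dplyr::left_join(grid, rows, by = c("i", "j"))
  if (!summarise) return(.new_sweep(rows, spec, "evolutionary_replicates"))
  out <- rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("i", "j",
                                                  names(spec$axes))))) |>
    dplyr::summarise(mean_final_mu = mean(.data$final_mu),
                     mean_final_sigma = mean(.data$final_sigma),
                     mean_final_h = mean(.data$final_h),
                     replicates = dplyr::n(),
                     .groups = "drop")
  .new_sweep(out, spec, "evolutionary")
}

#' Heteroplasmy distribution time series
#'
#' Bins the per-cell mutant fractions of every generation of a trajectory
#' into fixed-width bins, for population-structure displays (how
#' homoplasmic the population stays while adapting). Bins are
#' `[bin_lo, bin_lo + binwidth)`, with `h = 1` assigned to the top bin.
#'
#' @param traj An `odna_trajectory` run with `keep_cells = TRUE`, or a
#'   [sim_config()] (in which case the simulation is run first with
#'   `schedule`).
#' @param schedule Schedule used when `traj` is a config.
#' @param binwidth Bin width in mutant-fraction units, default 0.05.
#' @return A tibble with columns `generation`, `bin_lo`, `bin_hi`,
#'   `count`, `prop`.
#' @examples
#' traj <- run_simulation(sim_config(t_max = 20, seed = 1))
#' ts <- distribution_timeseries(traj, binwidth = 0.25)
#' @export
distribution_timeseries <- function(traj, schedule = env_schedule("switch"),
                                    binwidth = 0.05) {
  if (inherits(traj, "sim_config"))
    traj <- run_simulation(traj, schedule, keep_cells = TRUE)
  if (!("cells" %in% names(traj)))
    stop("trajectory lacks per-cell states; rerun with keep_cells = TRUE",
         call. = FALSE)
  nb <- ceiling(1 / binwidth)
  lo <- (seq_len(nb) - 1) * binwidth
  tibble::tibble(generation = traj$generation, cells = traj$cells) |>
    dplyr::mutate(cells = purrr::map(.data$cells, function(x) {
      h <- if (is.data.frame(x)) x$h else x
      b <- pmin(floor(h / binwidth), nb - 1) + 1
      tibble::tibble(bin = seq_len(nb), bin_lo = lo,
                     bin_hi = pmin(lo + binwidth, 1),
                     count = tabulate(b, nbins = nb),
                     prop = tabulate(b, nbins = nb) / length(h))
    })) |>
    tidyr::unnest("cells") |>
    dplyr::select(-"bin")
}
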