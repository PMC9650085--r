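#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a simulation trajectory
#'
#' Returns the per-generation records as a plain tibble (dropping the
#' per-cell list-column unless `keep_cells = TRUE`).
#'
#' @param x An `odna_trajectory`.
#' @param keep_cells Keep the `cells` list-column? Default `FALSE`.
#' @param ... Unused.
#' @return A tibble.
#' @examples
#' tidy(run_simulation(sim_config(t_max = 10, seed = 1)))
#' @method tidy odna_trajectory
#' @export
tidy.odna_trajectory <- function(x, keep_cells = FALSE, ...) {
  out <- tibble::as_tibble(x)
  if (!keep_cells && "cells" %in% names(out))
    out <- dplyr::select(out, -"cells")
  out
}

#' One-row summary of a simulation trajectory
#'
#' @param x An `odna_trajectory`.
#' @param threshold Adaptation threshold passed to [adaptation_time()].
#' @param ... Unused.
#' @return A one-row tibble with `generations`, `adapted`,
#'   `adaptation_time`, `final_mean_h`, `final_mean_fitness`, `extinct`,
#'   and (where tracked) `final_mean_mu`, `final_mean_sigma`,
#'   `final_mean_hD`.
#' @examples
#' glance(run_simulation(sim_config(t_max = 10, seed = 1)))
#' @method glance odna_trajectory
#' @export
glance.odna_trajectory <- function(x, threshold = 0.75, ...) {
  last <- nrow(x)
  at <- adaptation_time(x, threshold)
  out <- tibble::tibble(
    generations = x$generation[last],
    adapted = !is.na(at),
    adaptation_time = at,
    final_mean_h = x$mean_h[last],
    final_mean_fitness = x$mean_fitness[last],
    extinct = isTRUE(attr(x, "extinct")))
  if ("mean_mu" %in% names(x)) {
    out$final_mean_mu <- x$mean_mu[last]
    out$final_mean_sigma <- x$mean_sigma[last]
  }
  if ("mean_hD" %in% names(x)) out$final_mean_hD <- x$mean_hD[last]
  out
}

#' Tidy a sweep grid
#'
#' @param x An `odna_sweep`.
#' @param ... Unused.
#' @return The underlying tibble.
#' @method tidy odna_sweep
#' @export
tidy.odna_sweep <- function(x, ...) tibble::as_tibble(x)

#' One-row summary of a sweep grid
#'
#' @param x An `odna_sweep`.
#' @param ... Unused.
#' @return A one-row tibble with the grid dimensions, replicate count and,
#'   for adaptation sweeps, the fraction of fully censored pixels.
#' @method glance odna_sweep
#' @export
glance.odna_sweep <- function(x, ...) {
  spec <- attr(x, "spec")
  out <- tibble::tibble(
    pixels = nrow(dplyr::distinct(tibble::as_tibble(x)[c("i", "j")])),
    axis1 = names(spec$axes)[1],
    axis2 = names(spec$axes)[2],
    replicates = spec$replicates)
  if ("n_censored" %in% names(x))
    out$prop_pixels_censored <- mean(x$n_censored == x$replicates)
  out
}
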