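#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulation trajectory
#'
#' Population mean mutant fraction against generation, shaded by the
#' environment in force; evolvable runs additionally show the evolving
#' population means of the mutation rate and segregation strength, and
#' three-type runs the dysfunctional load.
#'
#' @param object An `odna_trajectory`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' autoplot(run_simulation(sim_config(t_max = 50, seed = 1)))
#' @method autoplot odna_trajectory
#' @export
autoplot.odna_trajectory <- function(object, ...) {
  df <- tidy(object)
  vars <- intersect(c("mean_h", "mean_fitness", "mean_mu", "mean_sigma",
                      "mean_hD"), names(df))
  long <- tidyr::pivot_longer(df[c("generation", "environment", vars)],
                              dplyr::all_of(vars),
                              names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$generation, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$quantity)) +
    ggplot2::geom_rug(data = df[df$environment == "B", ],
                      ggplot2::aes(x = .data$generation, y = NULL),
                      sides = "b", alpha = 0.3, length = ggplot2::unit(0.02, "npc")) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "generation", y = NULL,
                  caption = "rug marks generations spent in environment B") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot a sweep grid as a heatmap
#'
#' Tile heatmap over the two sweep axes. For adaptation sweeps the fill
#' defaults to the censored mean adaptation time; for evolutionary sweeps,
#' to the mean evolved segregation strength.
#'
#' @param object An `odna_sweep` (summarised form).
#' @param fill Name of the column to map to fill; default chosen by sweep
#'   type.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot odna_sweep
#' @export
autoplot.odna_sweep <- function(object, fill = NULL, ...) {
  spec <- attr(object, "spec")
  if (is.null(fill))
    fill <- if ("mean_adaptation_time" %in% names(object))
      "mean_adaptation_time" else "mean_final_sigma"
  ax <- names(spec$axes)
  df <- tibble::as_tibble(object)
  df[[ax[1]]] <- factor(df[[ax[1]]])
  df[[ax[2]]] <- factor(df[[ax[2]]])
  ggplot2::ggplot(df, ggplot2::aes(.data[[ax[1]]], .data[[ax[2]]],
                                   fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::theme_minimal()
}

#' Plot a heteroplasmy distribution time series
#'
#' Tile display of the per-generation histogram of cell-level mutant
#' fractions (see [distribution_timeseries()]).
#'
#' @param ts Output of [distribution_timeseries()].
#' @return A ggplot object.
#' @examples
#' traj <- run_simulation(sim_config(t_max = 20, seed = 1))
#' plot_h_distribution(distribution_timeseries(traj, binwidth = 0.25))
#' @export
plot_h_distribution <- function(ts) {
  ggplot2::ggplot(ts, ggplot2::aes(.data$generation,
                                   (.data$bin_lo + .data$bin_hi) / 2,
                                   fill = .data$prop)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "proportion\nof cells") +
    ggplot2::labs(x = "generation", y = "mutant fraction h") +
    ggplot2::theme_minimal()
}
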