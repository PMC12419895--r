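# Plotting helpers: inspection aids for the three standard views of the
# model (replicator phase portrait, adoption trajectories, sweep panels).

#' Phase portrait of the replicator dynamics
#'
#' Plots the rate of change `x'` against the social proportion `x`, with
#' the equilibria marked: filled points are stable, open points unstable.
#'
#' @param object A `ritual_equilibria` result from [find_equilibria()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ritual_equilibria
#' @export
autoplot.ritual_equilibria <- function(object, ...) {
  params <- attr(object, "params")
  curve <- tibble::tibble(x = seq(0, 1, length.out = 401))
  curve$rate <- replicator_step(curve$x, params)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$x, y = .data$rate)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = tibble::tibble(x = object$x, stability = object$stability,
                            rate = 0),
      ggplot2::aes(shape = .data$stability), size = 3, fill = "black"
    ) +
    ggplot2::scale_shape_manual(values = c(stable = 19, unstable = 21)) +
    ggplot2::labs(
      x = "proportion playing the social strategy, x",
      y = "replicator rate x'",
      title = sprintf("N = %d, M = %d, h = %g, s = %g",
                      params$N, params$M, params$h, params$s)
    ) +
    ggplot2::theme_minimal()
}

#' Adoption trajectories of a simulation
#'
#' One line per round showing the proportion of agents playing the social
#' strategy over the turns of the simulation; the dotted horizontal line
#' marks the attendance threshold `M/N`, and grey rug ticks mark turns where
#' the threshold was cleared (drawn for single-round data only).
#'
#' @param object A `ritual_sim` result from [run_experiment()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot ritual_sim
#' @export
autoplot.ritual_sim <- function(object, ...) {
  config <- attr(object, "config")
  p <- ggplot2::ggplot(
    object,
    ggplot2::aes(x = .data$turn, y = .data$prop_social,
                 group = .data$round)
  ) +
    ggplot2::geom_line(alpha = 0.5, colour = "darkgreen") +
    ggplot2::geom_hline(yintercept = config$M / config$N,
                        linetype = "dotted") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "turn", y = "proportion playing social strategy") +
    ggplot2::theme_minimal()
  if (length(unique(object$round)) == 1L) {
    cleared <- dplyr::filter(object, .data$threshold_cleared)
    p <- p + ggplot2::geom_rug(data = cleared, sides = "b",
                               colour = "grey50", alpha = 0.6)
  }
  p
}

#' Panel plot of a sweep summary
#'
#' Mean adoption trajectories faceted by environmental spread (columns) and
#' group size (rows), coloured by the initial pilgrim proportion.
#'
#' @param summary Output of [summarize_trajectories()] for a sweep that
#'   varied `p0`, `PV` and `N`.
#' @return A ggplot object.
#' @export
plot_sweep_summary <- function(summary) {
  stopifnot(all(c("p0", "PV", "N", "turn", "mean_prop_social") %in%
                  names(summary)))
  ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$turn, y = .data$mean_prop_social,
                 colour = factor(.data$p0))
  ) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(N ~ PV, labeller = ggplot2::label_both) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "turn", y = "mean proportion social",
                  colour = "initial\nproportion") +
    ggplot2::theme_minimal()
}
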