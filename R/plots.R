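#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a colony snapshot
#'
#' Cells drawn at their positions, colored by reporter state: GFP-on cells
#' green, optimal-but-immature cells olive, all others grey.
#'
#' @param object A `colony_state`.
#' @param ... Unused.
#' @export
autoplot.colony_state <- function(object, ...) {
  df <- colony_cells(object)
  df$state <- factor(
    ifelse(df$gfp, "GFP on", ifelse(df$optimal, "optimal (maturing)", "searching")),
    levels = c("searching", "optimal (maturing)", "GFP on")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_manual(values = c(
      "searching" = "grey55",
      "optimal (maturing)" = "olivedrab3",
      "GFP on" = "green3"
    ), drop = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = sprintf("colony at generation %.2f",
                                  colony_generation(object))) +
    ggplot2::theme_minimal()
}

#' Plot a colony run trajectory
#'
#' Population size and optimal / GFP-on cell counts over generations, with
#' the first-optimum generation marked.
#'
#' @param object A `colony_run`.
#' @param ... Unused.
#' @export
autoplot.colony_run <- function(object, ...) {
  tr <- tidy(object) |>
    tidyr::pivot_longer(c("n_cells", "n_optimal", "n_gfp"),
                        names_to = "series", values_to = "count")
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$generation,
                                        y = .data$count,
                                        colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "generation", y = "cells (log scale)",
                  colour = NULL) +
    ggplot2::theme_minimal()
  if (object$found) {
    p <- p + ggplot2::geom_vline(xintercept = object$first_optimum_generation,
                                 linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot a signal field
#'
#' @param object A `signal_field`.
#' @param ... Unused.
#' @export
autoplot.signal_field <- function(object, ...) {
  ax <- seq(-object$half, object$half, by = object$dx)
  df <- expand.grid(x = ax, y = ax)
  df$concentration <- as.vector(t(object$grid))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$concentration)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a Life grid
#'
#' @param object A `life_grid`.
#' @param ... Unused.
#' @export
autoplot.life_grid <- function(object, ...) {
  m <- unclass(object)
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df$live <- as.logical(m[cbind(df$row, df$col)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = -.data$row,
                                   fill = .data$live)) +
    ggplot2::geom_tile(colour = "grey85", linewidth = 0.2) +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_manual(values = c("FALSE" = "grey15",
                                          "TRUE" = "cyan3")) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot sweep means
#'
#' @param sweep The list returned by [run_sweep()].
#' @param censored Plot stop-censored means (default) or found-only means.
#' @export
plot_sweep <- function(sweep, censored = TRUE) {
  s <- sweep$summary
  s$mean <- if (censored) s$mean_censored else s$mean_found
  ggplot2::ggplot(s, ggplot2::aes(x = .data$value, y = .data$mean,
                                  colour = .data$implementation,
                                  group = .data$implementation)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::labs(x = unique(s$varied), y = "first optimum (generations)",
                  title = unique(s$table)) +
    ggplot2::theme_minimal()
}
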