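# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.gmls_nodes <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       colour = .data$kind)) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("GMLS node set (%d nodes)", nrow(object)),
                  x = NULL, y = NULL)
}

#' @export
autoplot.stokes_solution <- function(object, ...) {
  df <- object$nodes
  df$speed <- sqrt(object$u^2 + object$v^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$speed)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "|u|", x = NULL, y = NULL,
                  title = "Stokes velocity magnitude")
}

#' @export
autoplot.track_set <- function(object, ...) {
  ggplot2::ggplot(object$tracks,
                  ggplot2::aes(x = .data$x_um, y = .data$y_um,
                               group = .data$track_id,
                               colour = factor(.data$track_id))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "track", x = "x (um)", y = "y (um)",
                  title = "Microcolony tracks")
}

#' @export
autoplot.power_law_fit <- function(object, ...) {
  grid <- tibble::tibble(D = seq(min(object$data$D), max(object$data$D),
                                 length.out = 100))
  grid$N <- object$a * grid$D^object$b
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$D, y = .data$N)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "colony diameter D (um)", y = "base cells N",
                  title = sprintf("N = %.3g D^%.3g", object$a, object$b))
}

#' Histogram of weighted mean relative orientations
#'
#' @param stats An [orientation_stats()] tibble.
#' @param binwidth Degrees per bin (default 5).
#' @return A ggplot object.
#' @export
plot_orientation_histogram <- function(stats, binwidth = 5) {
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$mean_rel_angle)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey40") +
    ggplot2::coord_cartesian(xlim = c(0, 90)) +
    ggplot2::labs(x = "weighted mean relative angle (deg)", y = "cells")
}

#' @export
tidy.stokes_solution <- function(x, ...) {
  out <- x$nodes
  out$u <- x$u; out$v <- x$v; out$p <- x$p_hat
  tibble::as_tibble(out)
}

#' @export
glance.stokes_solution <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$nodes),
                 momentum_residual = x$residuals$momentum,
                 continuity_residual = x$residuals$continuity,
                 divergence_free = x$residuals$divfree,
                 estimator = x$residuals$estimator %||% NA_real_,
                 mode = x$mode)
}
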