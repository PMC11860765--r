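# ggplot2 views of the fitted objects and result tables.

#' @describeIn fit_dye_dilution Histogram of log-fluorescence with the
#'   fitted constrained mixture overlaid (dashed: component peaks).
#' @param object A `proliferation_fit`.
#' @param events Optionally, the event table the fit was made from, to draw
#'   the histogram under the fitted density.
#' @param channel Proliferation-dye channel name in `events`.
#' @param ... Ignored.
#' @export
autoplot.proliferation_fit <- function(object, events = NULL,
                                       channel = "proliferation_dye", ...) {
  gens <- 0:(object$n_peaks - 1L)
  means <- object$mu0 + gens * log(object$ratio)
  grid <- seq(min(means) - 4 * object$sigma, max(means) + 4 * object$sigma,
              length.out = 512)
  dens <- as.vector(vapply(gens, function(g)
    object$weights[g + 1] * dnorm(grid, means[g + 1], object$sigma),
    numeric(length(grid))) %*% rep(1, object$n_peaks))
  p <- ggplot2::ggplot()
  if (!is.null(events)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(lx = log(events[[channel]])),
      ggplot2::aes(x = .data$lx, y = ggplot2::after_stat(density)),
      bins = 120, fill = "grey80", colour = NA)
  }
  p +
    ggplot2::geom_line(data = tibble::tibble(x = grid, y = dens),
                       ggplot2::aes(.data$x, .data$y), colour = "#2166ac") +
    ggplot2::geom_vline(xintercept = means, linetype = "dashed",
                        colour = "grey50", linewidth = 0.3) +
    ggplot2::labs(x = "log fluorescence (a.u.)", y = "density",
                  title = sprintf("Halving-peak mixture: DI = %.2f (precursor-weighted)",
                                  division_index(object)))
}

#' @describeIn summarize_coloc Bar chart of colocalization events per
#'   nucleus.
#' @param object A `coloc_summary`.
#' @param ... Ignored.
#' @export
autoplot.coloc_summary <- function(object, ...) {
  ggplot2::ggplot(object$per_nucleus,
                  ggplot2::aes(x = factor(.data$n_events))) +
    ggplot2::geom_bar(fill = "#2166ac") +
    ggplot2::labs(x = "colocalization events per nucleus", y = "nuclei",
                  title = sprintf("%.0f%% of %d nuclei with >=1 event",
                                  100 * object$fraction_with_event, object$n_nuclei))
}

#' Plot a median focus patch
#'
#' Raster view of a per-cell median focus (or any patch), for visual
#' inspection of focus shape and background.
#'
#' @param patch Matrix, e.g. from [median_focus()].
#' @return A ggplot object.
#' @export
plot_median_focus <- function(patch) {
  df <- tidyr::expand_grid(row = seq_len(nrow(patch)), col = seq_len(ncol(patch)))
  df$value <- patch[cbind(df$row, df$col)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "a.u.") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "median focus")
}
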