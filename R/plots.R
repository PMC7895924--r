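#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a tessellation coloured by cell class or degree
#'
#' @param object An `"epi_tessellation"`.
#' @param fill Optional per-cell fill values (e.g. `classes$class` or
#'   degrees); defaults to neighbour number.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epi_tessellation <- function(object, fill = NULL, ...) {
  polys <- purrr::imap(object$polygons, function(p, i) {
    tibble(cell_id = i, x = p[, 1], y = p[, 2])
  })
  d <- bind_rows(polys)
  fills <- tibble(cell_id = object$cells$cell_id,
                  fill = fill %||% factor(object$cells$degree))
  d <- left_join(d, fills, by = "cell_id")
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, group = .data$cell_id,
                                  fill = .data$fill)) +
    ggplot2::geom_polygon(colour = "grey20", linewidth = 0.2) +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "ML (px)", y = "RC (px)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a Lewis'-law fit
#'
#' Apical area against neighbour number with the least-squares line.
#'
#' @param object A `"lewis_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lewis_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(.data$degree, .data$area)) +
    ggplot2::geom_jitter(width = 0.12, height = 0, alpha = 0.5) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "firebrick") +
    ggplot2::labs(x = "Neighbour number", y = "Apical area (px²)",
                  subtitle = sprintf("r = %.2f, p = %.2g, n = %d",
                                     object$pearson_r, object$p_value,
                                     object$n_cells)) +
    ggplot2::theme_minimal()
}

#' Plot orientation histogram with median marker
#'
#' @param object An `"orientation_histogram"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.orientation_histogram <- function(object, ...) {
  med <- attr(object, "median_deg")
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes((.data$bin_lo + .data$bin_hi) / 2, .data$count)) +
    ggplot2::geom_col(width = diff(c(object$bin_lo[1], object$bin_hi[1])),
                      fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = med, colour = "navy", linewidth = 1) +
    ggplot2::labs(x = "Apical long-axis orientation (°, 90 = ML)",
                  y = "Cells",
                  subtitle = sprintf("median %.1f°, n = %d", med,
                                     attr(object, "n"))) +
    ggplot2::theme_minimal()
}

#' Plot group mean traces with SEM ribbons
#'
#' Aligned mean apical-area traces (dilation at negative times,
#' constriction at positive times) per group.
#'
#' @param group_means Tibble from [group_mean_trace()].
#' @return A ggplot object.
#' @export
plot_group_traces <- function(group_means) {
  ggplot2::ggplot(group_means,
                  ggplot2::aes(.data$aligned_t, .data$mean,
                               colour = .data$group, fill = .data$group)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sem,
                                      ymax = .data$mean + .data$sem),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "Time from maximum area (min)",
                  y = "Apical area (% of cell maximum)",
                  colour = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}
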