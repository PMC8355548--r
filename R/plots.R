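#' Plot bead trajectories
#'
#' @param trajectories Tibble from [link_trajectories()].
#' @return A ggplot.
#' @export
plot_trajectories <- function(trajectories) {
  ggplot2::ggplot(trajectories,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data$bead_id,
                               colour = factor(.data$bead_id))) +
    ggplot2::geom_path(alpha = 0.7, show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Bead trajectories") +
    ggplot2::theme_minimal()
}

#' Plot the trajectory periodogram of one bead
#'
#' @param trajectories Trajectory tibble (one or more beads).
#' @param fps Frame rate.
#' @param bead Bead id to plot.
#' @param f_min Lower frequency bound shown.
#' @return A ggplot of per-axis spectral power vs frequency.
#' @export
plot_spectrum <- function(trajectories, fps, bead = 1, f_min = 0.5) {
  tr <- trajectories[trajectories$bead_id == bead, ]
  if (nrow(tr) == 0L) stop("no such bead", call. = FALSE)
  sp <- dplyr::bind_rows(
    dplyr::mutate(axis_spectrum(tr$x, fps), axis = "x"),
    dplyr::mutate(axis_spectrum(tr$y, fps), axis = "y")
  )
  sp <- sp[sp$freq >= f_min & sp$freq < fps / 2, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$freq, y = .data$power,
                                   colour = .data$axis)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "spectral power",
                  title = sprintf("Bead %s periodogram", bead)) +
    ggplot2::theme_minimal()
}

#' Plot fitted ROI ellipses over cell assignments
#'
#' @param ellipses Per-ROI tibble from [roi_ellipses()].
#' @param n_arc Points per ellipse outline.
#' @return A ggplot with one outline per ROI, coloured by cell.
#' @export
plot_roi_ellipses <- function(ellipses, n_arc = 60) {
  arcs <- ellipses |>
    dplyr::rowwise() |>
    dplyr::reframe({
      th <- seq(0, 2 * pi, length.out = n_arc)
      ca <- cos(.data$orientation); sa <- sin(.data$orientation)
      ex <- .data$a * cos(th); ey <- .data$b * sin(th)
      tibble::tibble(roi_id = .data$roi_id, cell_id = .data$cell_id,
                     x = .data$cx + ca * ex - sa * ey,
                     y = .data$cy + sa * ex + ca * ey)
    })
  ggplot2::ggplot(arcs, ggplot2::aes(x = .data$x, y = .data$y,
                                     group = .data$roi_id,
                                     colour = factor(.data$cell_id))) +
    ggplot2::geom_path(show.legend = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  title = "Minimum enclosing ellipses of basal-body ROIs") +
    ggplot2::theme_minimal()
}

#' Boxplots of marker scores by gate group
#'
#' @param object A `cq_marker_comparison` from [compare_marker_sets()].
#' @param ... Unused.
#' @return A ggplot, one facet per marker panel.
#' @exportS3Method ggplot2::autoplot
autoplot.cq_marker_comparison <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(x = .data$group, y = .data$score,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = sprintf("%s status", object$split_gene),
                  y = "marker score (CPM)") +
    ggplot2::theme_minimal()
}
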