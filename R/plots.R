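# ggplot2 autoplot methods. Plots use image-pixel convention (y increases
# downward), so the y axis is reversed to show faces upright.

#' Plot an aligned landmark sample
#'
#' Shows every aligned configuration as a translucent point cloud with the
#' consensus shape on top.
#'
#' @param object A [gpa()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot facecue_gpa
#' @export
autoplot.facecue_gpa <- function(object, ...) {
  ggplot2::ggplot(object$aligned, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(group = .data$face_id),
                        alpha = 0.15, size = 0.6, colour = "grey30") +
    ggplot2::geom_point(data = object$consensus, colour = "firebrick",
                        size = 1.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Procrustes-aligned landmarks",
                  subtitle = sprintf("%d faces, %d landmarks; consensus in red",
                                     length(object$ids), object$n_points),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a dimorphism axis
#'
#' Arrows from the female mean landmark positions to the male mean
#' positions, magnified for visibility.
#'
#' @param object A [dimorphism_axis()] result.
#' @param magnify Displacement magnification factor (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dimorphism_axis
#' @export
autoplot.dimorphism_axis <- function(object, magnify = 3, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$female_x, y = .data$female_y)) +
    ggplot2::geom_point(colour = "grey40", size = 0.8) +
    ggplot2::geom_segment(
      ggplot2::aes(xend = .data$female_x + magnify * .data$dx,
                   yend = .data$female_y + magnify * .data$dy),
      arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm")),
      colour = "steelblue"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = "Female-to-male shape displacement",
      subtitle = sprintf("arrows magnified %gx; |v| = %.4g", magnify,
                         sqrt(object$norm_sq)),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Plot dimorphism scores
#'
#' Histogram of the raw projection scores (0 = female mean, 1 = male mean).
#'
#' @param object A [score_faces()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dimorphism_scores
#' @export
autoplot.dimorphism_scores <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$raw)) +
    ggplot2::geom_histogram(bins = 30, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = c(0, 1), linetype = "dashed") +
    ggplot2::labs(title = "Sexual-dimorphism scores",
                  subtitle = "dashed: female mean (0) and male mean (1); higher = more male-like",
                  x = "raw projection score", y = "faces") +
    ggplot2::theme_minimal()
}

#' Plot standardized effects with confidence intervals
#'
#' Standardized betas with 95% confidence intervals per outcome, faceted by
#' sample and focal predictor; point shape marks the effect term.
#'
#' @param object A [run_analysis()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot facecue_analysis
#' @export
autoplot.facecue_analysis <- function(object, ...) {
  eff <- object$effects |>
    dplyr::mutate(
      lo = .data$beta - qt(0.975, .data$df) * .data$se,
      hi = .data$beta + qt(0.975, .data$df) * .data$se
    )
  ggplot2::ggplot(eff, ggplot2::aes(x = .data$beta, y = .data$outcome,
                                    colour = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(ggplot2::vars(.data$sample),
                        ggplot2::vars(.data$focal)) +
    ggplot2::labs(title = "Standardized effects (95% CI)",
                  x = "standardized beta", y = NULL, colour = "effect") +
    ggplot2::theme_minimal()
}
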