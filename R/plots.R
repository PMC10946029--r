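# ggplot2 views of the main result types.

#' Plot a tuning map with its fitted tuning function
#'
#' @param map `"tuning_map"`.
#' @param fit optional `"tuning_fit"` overlaid as a curve.
#' @return a ggplot.
#' @export
plot_tuning_map <- function(map, fit = NULL) {
  feature <- attr(map, "feature") %||% "feature"
  p <- ggplot2::ggplot(map, ggplot2::aes(x = .data$mid, y = .data$norm)) +
    ggplot2::geom_col(width = diff(map$mid[1:2]) * 0.9, fill = "grey60") +
    ggplot2::labs(x = feature, y = "normalized mean spikes") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    xx <- seq(min(map$lo), max(map$hi), length.out = 200)
    xf <- if (feature == "orientation") xx * pi / 180 else xx
    yy <- if (fit$family == "gaussian")
      fit$a * exp(-(xf - fit$b)^2 / fit$c^2)
    else fit$a * cos(xf - fit$c) + fit$d
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(mid = xx, norm = yy), color = "firebrick")
  }
  p
}

#' @method autoplot population_map
#' @export
autoplot.population_map <- function(object, colour = NULL, ...) {
  df <- object$coords
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$axis1, y = .data$axis2)) +
    ggplot2::labs(x = "primary axis", y = "secondary axis") +
    ggplot2::theme_minimal()
  if (is.null(colour)) p + ggplot2::geom_point()
  else p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
    ggplot2::labs(colour = "")
}

#' Plot a moving-window axis profile
#'
#' @param profile output of [axis_profile()].
#' @return a ggplot with the smoothed profile and its dispersion band.
#' @export
plot_axis_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$center, y = .data$value)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$value - .data$sd,
                                      ymax = .data$value + .data$sd),
                         fill = "steelblue", alpha = 0.2) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::labs(x = "axis coordinate", y = "windowed value") +
    ggplot2::theme_minimal()
}

#' @method autoplot cross_tuning
#' @export
autoplot.cross_tuning <- function(object, which = c("normalized", "counts",
                                                    "density"), ...) {
  which <- match.arg(which)
  M <- object[[which]]
  ce <- object$closure_edges; ke <- object$curvature_edges
  df <- tibble::as_tibble(expand.grid(
    closure = (ce[-length(ce)] + ce[-1]) / 2,
    curvature = (ke[-length(ke)] + ke[-1]) / 2))
  df$value <- as.numeric(M)      # row = closure bin, col = curvature bin
  ggplot2::ggplot(df, ggplot2::aes(x = .data$closure, y = .data$curvature,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::labs(fill = which) +
    ggplot2::theme_minimal()
}
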