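# ggplot2 visualizations of the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a synthetic scene with its ground truth
#'
#' Renders the scene raster with the ground-truth marker centroids,
#' rectangle axis and plumb line overlaid.
#'
#' @param object A `posture_scene` from [render_view()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posture_scene <- function(object, ...) {
  img <- object$image
  gt <- object$ground_truth
  h <- dim(img)[1]; w <- dim(img)[2]
  raster <- grDevices::rgb(img[, , 1], img[, , 2], img[, , 3])
  dim(raster) <- c(h, w)
  seg <- tibble::tibble(
    x = c(gt$rectangle_endpoints[1, 1], gt$plumb_endpoints[1, 1]),
    y = c(gt$rectangle_endpoints[1, 2], gt$plumb_endpoints[1, 2]),
    xend = c(gt$rectangle_endpoints[2, 1], gt$plumb_endpoints[2, 1]),
    yend = c(gt$rectangle_endpoints[2, 2], gt$plumb_endpoints[2, 2]),
    what = c("scale rectangle", "plumb line"))
  ggplot2::ggplot() +
    ggplot2::annotation_raster(raster, xmin = 0.5, xmax = w + 0.5,
                               ymin = -(h + 0.5), ymax = -0.5) +
    ggplot2::geom_point(data = gt$markers,
                        ggplot2::aes(x = .data$x_px, y = -.data$y_px),
                        shape = 3, size = 2, color = "black") +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = -.data$y,
                                       xend = .data$xend, yend = -.data$yend,
                                       linetype = .data$what),
                          color = "black") +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(-h, 0), expand = FALSE) +
    ggplot2::labs(x = "x (px)", y = "-y (px)", linetype = NULL,
                  title = paste("Synthetic scene:", object$spec$view)) +
    ggplot2::theme_minimal()
}

#' Plot a landmark set
#'
#' @param object A `landmark_set`.
#' @param ... Unused.
#' @return A ggplot of landmark pixel positions colored by provenance.
#' @export
autoplot.landmark_set <- function(object, ...) {
  df <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$x_px))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x_px, y = -.data$y_px,
                                   color = .data$provenance)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$site,
                                                   ifelse(.data$side == "none",
                                                          "", paste0("_", .data$side)))),
                       size = 2.4, vjust = -0.8, show.legend = FALSE) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("Landmarks:", attr(object, "view")),
                  x = "x (px)", y = "-y (px)", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a validation report
#'
#' Dot plot of per-feature mean differences with the equivalence bounds
#' each feature needed, colored by the equivalence decision.
#'
#' @param object A `posture_validation`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posture_validation <- function(object, ...) {
  al <- attr(object, "config")$alphas
  eq_col <- paste0("equivalent_", al[1])
  df <- dplyr::mutate(tibble::as_tibble(object),
                      equivalent = .data[[eq_col]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean_diff,
                                   y = stats::reorder(.data$feature,
                                                      .data$mean_diff))) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$tost_lower,
                                         xmax = .data$tost_upper),
                            height = 0, color = "grey70") +
    ggplot2::geom_point(ggplot2::aes(color = .data$equivalent)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "mean difference (native units)", y = NULL,
                  color = sprintf("equivalent (alpha = %g)", al[1])) +
    ggplot2::theme_minimal()
}

#' Plot a classifier evaluation
#'
#' Confusion-matrix heat map with counts.
#'
#' @param object A `posture_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.posture_eval <- function(object, ...) {
  df <- as.data.frame(as.table(object$confusion))
  names(df) <- c("truth", "predicted", "n")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(title = sprintf("Accuracy %.1f%%", object$accuracy)) +
    ggplot2::theme_minimal()
}
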