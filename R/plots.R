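#' Plot a contact map
#'
#' @param object a [contact_map].
#' @param ... unused.
#' @return a ggplot object (upper triangle shows contacts; masked pairs
#'   are greyed).
#' @method autoplot contact_map
#' @export
autoplot.contact_map <- function(object, ...) {
  idx <- which(upper.tri(object$map), arr.ind = TRUE)
  df <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                       state = dplyr::case_when(
                         object$mask[idx] ~ "masked",
                         object$map[idx] ~ "contact",
                         TRUE ~ "none"))
  ggplot2::ggplot(dplyr::filter(df, .data$state != "none"),
                  ggplot2::aes(x = .data$j, y = .data$i,
                               colour = .data$state)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse(limits = c(object$length, 1)) +
    ggplot2::scale_x_continuous(limits = c(1, object$length)) +
    ggplot2::scale_colour_manual(values = c(contact = "grey25",
                                            masked = "grey80")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue j", y = "residue i", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a prediction map
#'
#' @param object a [prediction_map].
#' @param truth optional [contact_map]; when given, the lower triangle
#'   shows the true contacts for comparison.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot prediction_map
#' @export
autoplot.prediction_map <- function(object, truth = NULL, ...) {
  idx <- which(upper.tri(object$scores), arr.ind = TRUE)
  df <- tibble::tibble(i = idx[, 1], j = idx[, 2],
                       score = object$scores[idx])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                        fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "residue j", y = "residue i",
                  fill = object$method) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tidx <- which(lower.tri(truth$map) & truth$map, arr.ind = TRUE)
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(i = tidx[, 1], j = tidx[, 2]),
      ggplot2::aes(x = .data$j, y = .data$i), inherit.aes = FALSE,
      size = 0.5, colour = "grey40")
  }
  p
}

#' Per-layer PPV curves
#'
#' Plots the mean top-L PPV per layer from an [evaluate_stack()] table or
#' a stack's training history.
#'
#' @param x tibble from [evaluate_stack()] (columns `layer`, `ppv`) or a
#'   [contact_stack].
#' @return a ggplot object.
#' @export
plot_layer_ppv <- function(x) {
  if (inherits(x, "contact_stack")) {
    df <- tidyr::pivot_longer(x$history, cols = c("ppv_insample", "ppv_oof"),
                              names_to = "series", values_to = "ppv")
    df <- dplyr::filter(df, !is.na(.data$ppv))
  } else {
    df <- dplyr::summarise(dplyr::group_by(x, .data$layer),
                           ppv = mean(.data$ppv), .groups = "drop")
    df$series <- "mean test PPV"
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$layer, y = .data$ppv,
                                   colour = .data$series)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "layer", y = "top-L PPV", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot neighbourhood histograms of contact maps
#'
#' @param stats tibble from [window_contact_statistics()].
#' @return a ggplot object.
#' @export
plot_window_statistics <- function(stats) {
  ggplot2::ggplot(dplyr::filter(stats, !is.na(.data$frequency)),
                  ggplot2::aes(x = .data$neighbours, y = .data$frequency,
                               linetype = .data$centre)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "contacts among window neighbours", y = "frequency",
                  linetype = "centre pair") +
    ggplot2::theme_minimal()
}
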