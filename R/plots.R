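# ggplot2 graphics for the main result types.

#' Phasor plot with the universal semicircle
#'
#' @param points Per-point feature table from [phasor_features()].
#' @param channel Channel id 1..5.
#' @param color Optional column name used for the point color (e.g. a tissue
#'   label carried through from a synthetic scan).
#' @return A ggplot.
#' @export
plot_phasor <- function(points, channel = 1L, color = NULL) {
  gcol <- paste0("g_ch", channel)
  scol <- paste0("s_ch", channel)
  semi <- tibble::tibble(theta = seq(0, pi, length.out = 181)) |>
    dplyr::mutate(g = 0.5 + 0.5 * cos(.data$theta),
                  s = 0.5 * sin(.data$theta))
  p <- ggplot2::ggplot(dplyr::filter(points, .data$qc_all)) +
    ggplot2::geom_path(data = semi, ggplot2::aes(.data$g, .data$s),
                       linetype = "dashed", color = "grey40") +
    ggplot2::coord_fixed(xlim = c(0, 1), ylim = c(0, 0.6)) +
    ggplot2::labs(x = "g", y = "s",
                  title = sprintf("Phasor plot, channel %d", channel)) +
    ggplot2::theme_minimal()
  aes_pt <- if (is.null(color)) {
    ggplot2::aes(.data[[gcol]], .data[[scol]])
  } else {
    ggplot2::aes(.data[[gcol]], .data[[scol]], color = .data[[color]])
  }
  p + ggplot2::geom_point(aes_pt, alpha = 0.6, size = 0.8)
}

#' @export
autoplot.phb_map <- function(object, ...) {
  df <- tibble::tibble(
    x = rep(seq_len(ncol(object$map)), each = nrow(object$map)),
    y = rep(seq_len(nrow(object$map)), times = ncol(object$map)),
    value = as.vector(object$map)
  )
  lab <- if (object$kind == "probability") "P(malignant)" else "value"
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = lab, na.value = "grey90",
                                  limits = if (object$kind == "probability")
                                    c(0, 1) else NULL) +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal()
}

#' @export
autoplot.repeat_eval <- function(object, ...) {
  mc <- object$mean_curve
  ggplot2::ggplot(mc, ggplot2::aes(.data$fpr, .data$tpr_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$tpr_mean - .data$tpr_sd, 0),
      ymax = pmin(.data$tpr_mean + .data$tpr_sd, 1)), alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "Average ROC over repeated cross-validation") +
    ggplot2::theme_minimal()
}

#' Bar chart of predictor importance
#'
#' @param imp Output of [predictor_importance()] or
#'   [aggregate_by_channel()].
#' @return A ggplot.
#' @export
plot_importance <- function(imp) {
  xcol <- if ("feature" %in% names(imp)) "feature" else "channel"
  ggplot2::ggplot(imp, ggplot2::aes(
    stats::reorder(.data[[xcol]], .data$importance),
    .data$importance)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Relative importance") +
    ggplot2::theme_minimal()
}
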