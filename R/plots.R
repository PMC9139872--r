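#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a red-value histogram
#'
#' Column plot of pixel counts against red value, the bisection view used
#' to pick and sanity-check erythema thresholds.
#'
#' @param object A `red_histogram`.
#' @param threshold Optional red threshold drawn as a vertical line.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot red_histogram
#' @export
autoplot.red_histogram <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object),
                       ggplot2::aes(x = .data$red_value, y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "firebrick") +
    ggplot2::labs(x = "red value", y = "pixels") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_vline(xintercept = threshold, linetype = "dashed")
  }
  p
}

#' Bland-Altman agreement plot
#'
#' Paired differences against paired means with the bias and limits of
#' agreement drawn as horizontal lines.
#'
#' @param object A `bland_altman` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = object$bias, color = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed", color = "grey40") +
    ggplot2::labs(x = "mean of methods", y = "difference (a - b)") +
    ggplot2::theme_minimal()
}

#' Calibration standard-curve plot
#'
#' The fitted erythema-standard line over its (concentration, response)
#' points, annotated with the equation and R-squared.
#'
#' @param object A `calibration_curve` fitted by [fit_standard()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot calibration_curve
#' @export
autoplot.calibration_curve <- function(object, ...) {
  if (is.null(object$model)) {
    stop("only fitted curves (from fit_standard()) carry plottable points",
         call. = FALSE)
  }
  df <- tibble::tibble(concentration = object$model$model$conc,
                       response = object$model$model$resp)
  lab <- sprintf("y = %.4f x %+.4f   R² = %.4f",
                 object$slope, object$intercept, object$r_squared)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration,
                                   y = .data$response)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         color = "firebrick") +
    ggplot2::labs(x = "blood volume fraction", y = "response",
                  subtitle = lab) +
    ggplot2::theme_minimal()
}

#' Relief-map heat view
#'
#' 2D rendering of the 3D color-density relief: tile height encoded as
#' fill.
#'
#' @param object A `relief_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot relief_map
#' @export
autoplot.relief_map <- function(object, ...) {
  df <- tibble::tibble(
    row = rep(seq_len(nrow(object)), times = ncol(object)),
    col = rep(seq_len(ncol(object)), each = nrow(object)),
    height = as.vector(unclass(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$height)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  fill = paste0(attr(object, "channel"), " density")) +
    ggplot2::theme_minimal()
}
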