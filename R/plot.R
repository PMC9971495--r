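#' Plot a deposition field
#'
#' Draws each fibre as a line segment at its true position, length and
#' orientation, coloured by bundle membership.
#'
#' @param object A `deposition_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot deposition_field
#' @export
autoplot.deposition_field <- function(object, ...) {
  fb <- object$fibres
  half <- fb$length_um / 2
  df <- dplyr::mutate(
    fb,
    x0 = .data$x - half * cos(.data$orientation),
    x1 = .data$x + half * cos(.data$orientation),
    y0 = .data$y - half * sin(.data$orientation),
    y1 = .data$y + half * sin(.data$orientation),
    bundled = duplicated(.data$bundle_id) |
      duplicated(.data$bundle_id, fromLast = TRUE)
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$bundled),
      linewidth = 0.4
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey30", `TRUE` = "firebrick"),
      name = "in bundle"
    ) +
    ggplot2::coord_fixed(
      xlim = c(0, object$substrate_width),
      ylim = c(object$substrate_height, 0)
    ) +
    ggplot2::labs(
      x = "x (µm)", y = "y (µm)",
      title = sprintf("%s deposition, %d fibres", object$model_tag,
                      nrow(fb))
    ) +
    ggplot2::theme_minimal()
}

#' Plot a calibrated grayscale image
#'
#' @param object A `raster_image`.
#' @param ... Unused.
#' @return A ggplot (grey raster in physical coordinates).
#' @method autoplot raster_image
#' @export
autoplot.raster_image <- function(object, ...) {
  ps <- object$pixel_size
  df <- tidyr::expand_grid(
    row = seq_len(nrow(object$pixels)),
    col = seq_len(ncol(object$pixels))
  )
  df$value <- as.vector(t(object$pixels))
  ggplot2::ggplot(df, ggplot2::aes(
    x = (.data$col - 0.5) * ps, y = (.data$row - 0.5) * ps,
    fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a class histogram
#'
#' Bars of per-mm2 normalised counts with the cumulative percentage
#' overlaid, matching the reporting-table layout.
#'
#' @param object A `class_histogram`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot class_histogram
#' @export
autoplot.class_histogram <- function(object, ...) {
  df <- tidy(object)
  df$class <- factor(df$class, levels = df$class)
  scale <- max(df$per_mm2, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$per_mm2), fill = "steelblue") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$cumulative_pct / 100 * scale, group = 1),
      colour = "firebrick"
    ) +
    ggplot2::geom_point(
      ggplot2::aes(y = .data$cumulative_pct / 100 * scale),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(
      name = "objects per mm²",
      sec.axis = ggplot2::sec_axis(~ . / scale * 100,
                                   name = "cumulative (%)")
    ) +
    ggplot2::labs(x = "class") +
    ggplot2::theme_minimal()
}

#' Plot counted fibre lengths
#'
#' @param object A `counting_result`.
#' @param bin_width,start Passed to [fibre_length_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot counting_result
#' @export
autoplot.counting_result <- function(object, bin_width = 3, start = 5, ...) {
  autoplot(fibre_length_histogram(object, bin_width, start)) +
    ggplot2::labs(x = "fibre length class (µm)")
}
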