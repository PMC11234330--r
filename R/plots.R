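#' Plot a depth map
#'
#' @param object A `depth_map`.
#' @param ... Unused.
#' @return A ggplot raster of the clearance with the feature footprint.
#' @export
autoplot.depth_map <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "clearance (µm)") +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "x (µm, downstream)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot a flow field
#'
#' Speed raster with a sub-sampled vector overlay.
#'
#' @param object A `flow_field`.
#' @param vector_every Draw one arrow per this many grid cells (0 = none).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.flow_field <- function(object, vector_every = 15, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$speed)) +
    ggplot2::scale_fill_viridis_c(name = "speed (µm/s)") +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "x (µm)",
                  y = if (identical(object$plane, "xz")) "z (µm)"
                      else "y (µm)") +
    ggplot2::theme_minimal()
  if (vector_every > 0) {
    ds <- object$spacing * vector_every
    sub <- df |>
      dplyr::filter(
        (round(.data$x / object$spacing - 0.5) %% vector_every) == 0,
        (round(.data$y / object$spacing - 0.5) %% vector_every) == 0,
        .data$speed > 0)
    sc <- ds / max(sub$speed)
    p <- p + ggplot2::geom_segment(
      data = sub,
      ggplot2::aes(xend = .data$x + .data$u * sc,
                   yend = .data$y + .data$v * sc),
      linewidth = 0.2, colour = "white",
      arrow = ggplot2::arrow(length = ggplot2::unit(0.03, "inches")))
  }
  p
}

#' Plot a scalar field
#'
#' @param object A `scalar_field`.
#' @param ... Unused.
#' @return A ggplot raster.
#' @export
autoplot.scalar_field <- function(object, ...) {
  unit <- switch(object$kind, vorticity = "s⁻¹",
                 q_criterion = "s⁻²", speed = "µm/s", "")
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$x, .data$y,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0(object$kind, " (", unit, ")")) +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::labs(x = "x (µm)", y = "y (µm)") +
    ggplot2::theme_minimal()
}

#' Plot an intensity profile
#'
#' @param object An `intensity_profile`.
#' @param ... Unused.
#' @return A ggplot line plot of mean fluorescence versus downstream
#'   distance.
#' @export
autoplot.intensity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$intensity)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "distance (µm, downstream)",
                  y = "mean fluorescence (counts)") +
    ggplot2::theme_minimal()
}

#' Display a single frame
#'
#' @param stack A `frame_stack`.
#' @param i Frame index.
#' @return A ggplot raster of the frame.
#' @export
plot_frame <- function(stack, i = 1) {
  f <- stack$frames[[i]]
  df <- tibble::tibble(
    x = rep(seq_len(ncol(f)), each = nrow(f)),
    y = rep(seq_len(nrow(f)), times = ncol(f)),
    value = as.vector(f)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "green",
                                 name = "counts") +
    ggplot2::coord_equal(expand = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
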