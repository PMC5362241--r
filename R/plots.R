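#' Space-time plot of a simulation record
#'
#' Renders the chosen field as a raster with space horizontal and time
#' vertical, the orientation of a kymograph.
#'
#' @param object A `spacetime_record`.
#' @param field `"rho"`, `"m"` or `"v"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spacetime_record <- function(object, field = c("rho", "m", "v"), ...) {
  field <- match.arg(field)
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$time,
    fill = .data[[field]]
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = field) +
    ggplot2::labs(
      x = "position (length units)", y = "time",
      title = sprintf(
        "Pe = %g, alpha = %g (%s)",
        object$mp$pe, object$kp$alpha, object$mp$advection_mode
      )
    ) +
    ggplot2::theme_minimal()
}

#' Zone width versus time
#'
#' @param object A `zone_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.zone_trace <- function(object, ...) {
  ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$time, y = .data$width)
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "zone width (RhoA integral)") +
    ggplot2::theme_minimal()
}

#' Kymograph image
#'
#' @param object A `kymograph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.kymograph <- function(object, ...) {
  np <- ncol(object$intensity)
  df <- tibble::tibble(
    time = rep(object$times, each = np),
    x = rep((seq_len(np) - 0.5) * object$pixel_size, length(object$times)),
    intensity = as.vector(t(object$intensity))
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$x, y = .data$time,
    fill = .data$intensity
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "position", y = "time") +
    ggplot2::theme_minimal()
}

#' Phase portrait of the well-mixed kinetics
#'
#' Nullclines, fixed points and (in the bistable regime) the separatrix of
#' the two-variable RhoA-NMIIA system.
#'
#' @param p A [kinetic_params()] object.
#' @param max_c Plot range.
#' @return A ggplot object.
#' @export
plot_phase_portrait <- function(p, max_c = 1.2) {
  nc <- nullclines(p, max_c = max_c)
  fp <- find_fixed_points(p)
  g <- ggplot2::ggplot() +
    ggplot2::geom_path(
      data = nc,
      ggplot2::aes(.data$rho, .data$m,
        colour = .data$curve,
        group = .data$curve
      )
    ) +
    ggplot2::geom_point(
      data = tidy(fp),
      ggplot2::aes(.data$rho, .data$m, shape = .data$stability),
      size = 3
    )
  if (attr(fp, "is_bistable")) {
    sep <- separatrix(p)
    g <- g + ggplot2::geom_path(
      data = tibble::as_tibble(sep),
      ggplot2::aes(.data$rho, .data$m, group = .data$branch),
      linetype = "dashed"
    )
  }
  g +
    ggplot2::coord_cartesian(xlim = c(0, max_c), ylim = c(0, max_c)) +
    ggplot2::labs(x = "[RhoA]", y = "[NMIIA]") +
    ggplot2::theme_minimal()
}

#' Width and intensity of the stationary-zone scan
#'
#' @param tab A [width_vs_pe()] table.
#' @return A ggplot object.
#' @export
plot_width_vs_pe <- function(tab) {
  ggplot2::ggplot(
    dplyr::filter(tab, .data$bounded == "stationary"),
    ggplot2::aes(.data$pe, .data$width)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Peclet number", y = "stationary zone width") +
    ggplot2::theme_minimal()
}
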