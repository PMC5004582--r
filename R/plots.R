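#' Plot an osmoshock trajectory
#'
#' Faceted view of the simulated response: volume, Hog1 activation,
#' controller outputs, glycerol pools and the turgor error against time.
#'
#' @param object An `osmo_trajectory` tibble from [simulate_osmo()].
#' @param vars Columns to facet over.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.osmo_trajectory <- function(object,
                                     vars = c("V", "uHOG", "uFps1",
                                              "vHOG", "Gly", "e"),
                                     ...) {
  long <- tidyr::pivot_longer(object[, c("time", vars)],
                              -"time", names_to = "quantity")
  long$quantity <- factor(long$quantity, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = paste0(attr(object, "scheme") %||% "",
                                 "  shock ",
                                 attr(object, "shock")$label %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a generic closed-loop trajectory
#'
#' Output, error and control signal against time.
#'
#' @param object A `loop_trajectory` tibble from [simulate_loop()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loop_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(object, -"time", names_to = "signal")
  long$signal <- factor(long$signal, levels = c("y", "e", "u"))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(colour = "#b2182b") +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = paste("controller:",
                                attr(object, "ctrl")$kind %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a fitted scheme against its data
#'
#' Overlays the fitted model's volume and Hog1 curves on the dataset the
#' fit was computed from, per shock.
#'
#' @param object An `osmo_fit` from [fit_scheme()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.osmo_fit <- function(object, ...) {
  data <- object$data
  grids <- split(data, data$shock_id)
  model <- dplyr::bind_rows(lapply(grids, function(d) {
    tr <- .sample_trajectory(object$scheme,
                             shock_input(d$shock_id[1],
                                         t_on = object$t_on),
                             object$params, sort(unique(d$time)))
    tibble::tibble(shock_id = d$shock_id[1], time = sort(unique(d$time)),
                   volume = tr$V, hog1 = tr$uHOG)
  }))
  d_long <- tidyr::pivot_longer(data, c("volume", "hog1"),
                                names_to = "channel")
  m_long <- tidyr::pivot_longer(model, c("volume", "hog1"),
                                names_to = "channel")
  ggplot2::ggplot(d_long, ggplot2::aes(.data$time, .data$value,
                                       colour = factor(.data$shock_id))) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::geom_line(data = m_long) +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = NULL, colour = "shock (M NaCl)",
                  title = paste("fitted scheme:", object$scheme$name)) +
    ggplot2::theme_minimal()
}
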