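# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' Tidy a ring trace into its per-quantity peak summary
#'
#' @param x A `ring_trace` from [simulate_ring()].
#' @param ... Unused.
#' @return The [summarise_response()] tibble.
#' @export
tidy.ring_trace <- function(x, ...) {
  summarise_response(x)
}

#' One-row overview of a ring simulation
#'
#' @param x A `ring_trace` from [simulate_ring()].
#' @param ... Unused.
#' @return A one-row tibble: the dimensionless groups, the zero-order
#'   natural frequency product omega0 * t_char, the static equilibrium
#'   displacement at the systolic level, peak displacement, and the
#'   divergence/collapse flags.
#' @export
glance.ring_trace <- function(x, ...) {
  g <- attr(x, "groups")
  nf <- if (g$law == "linear") {
    tibble::tibble(omega0_tchar = sqrt(linear_khat(g$base_law, g$material_ratio, g$lam_z0)),
                   oscillatory = TRUE)
  } else {
    natural_frequency(g$law, g$material_ratio, g$lam_z0)
  }
  xeq <- tryCatch(suppressWarnings(static_equilibrium(g)), error = function(e) NA_real_)
  tibble::tibble(
    law = g$law, order = g$order, material_ratio = g$material_ratio,
    p_hat_s = g$p_hat_s, lam_z0 = g$lam_z0, time_ratio = g$time_ratio,
    duty = g$duty, pressure_ratio = g$pressure_ratio,
    omega0_tchar = nf$omega0_tchar, oscillatory = nf$oscillatory,
    x_static = xeq,
    x_peak = max(abs(x$x)) * sign(x$x[which.max(abs(x$x))]),
    diverged = isTRUE(attr(x, "diverged")),
    collapsed = isTRUE(attr(x, "collapsed"))
  )
}

#' Plot a response trace
#'
#' Normalized radial displacement (with the strain-energy density and the
#' driving pressure) against physical time.
#'
#' @param object A `ring_trace`.
#' @param quantities Trace columns to facet over.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ring_trace <- function(object,
                                quantities = c("x", "W_norm", "p_hat"), ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), dplyr::all_of(c("t", quantities))),
    -"t", names_to = "quantity", values_to = "value")
  df$quantity <- factor(df$quantity, levels = quantities)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~quantity, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time [s]", y = NULL,
                  title = paste("Ring response,", attr(object, "groups")$law, "law"))
}

#' Plot a response spectrum
#'
#' Peak response against the swept parameter, one line per level of the
#' second condition column if the sweep is two-dimensional.
#'
#' @param object A `ring_sweep` from [sweep_response()].
#' @param quantity Which peak column to plot (default the displacement).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ring_sweep <- function(object, quantity = "x_peak", ...) {
  varying <- attr(object, "varying")
  xcol <- varying[1]
  p <- if (length(varying) >= 2) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[xcol]], y = .data[[quantity]],
                                         colour = factor(.data[[varying[2]]]))) +
      ggplot2::labs(colour = varying[2])
  } else {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[xcol]], y = .data[[quantity]]))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = xcol, y = quantity, title = "Peak-response spectrum")
}
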