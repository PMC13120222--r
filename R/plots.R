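#' Plot a post-illumination decay fit
#'
#' The measured flux trace with the dark transition, steady-state and dark
#' baseline levels, and the fitted exponential over the initial window.
#'
#' @param object A `decay_fit` from [analyze_decay()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot decay_fit
#' @export
autoplot.decay_fit <- function(object, ...) {
  r <- object$result
  d <- object$data
  w <- object$windows
  tfit <- seq(r$t_off, min(max(d$time_s), r$t_off + 6 / max(r$k_loglin, 1e-6)),
              length.out = 200)
  fit_line <- tibble::tibble(
    time_s = tfit,
    flux = r$e_dark + (r$e_ss - r$e_dark) * exp(-r$k_loglin * (tfit - r$t_off))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time_s, y = .data$flux)) +
    ggplot2::geom_line(colour = "grey40", linewidth = 0.3) +
    ggplot2::geom_line(data = fit_line, colour = "#D55E00", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = r$t_off, linetype = 2) +
    ggplot2::geom_hline(yintercept = c(r$e_ss, r$e_dark),
                        linetype = 3, colour = "grey30") +
    ggplot2::annotate("rect", xmin = r$t_off, xmax = r$t_off + w$initial_window,
                      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "#0072B2") +
    ggplot2::labs(
      x = "time (s)", y = expression(paste("isoprene flux (nmol ", m^-2, " ", s^-1, ")")),
      title = sprintf("S_pool = %.0f nmol m-2, k = %.3f s-1", r$s_pool, r$k_loglin)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a sigmoid temperature-response fit
#'
#' @param object A `sigmoid_fit` from [fit_sigmoid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sigmoid_fit
#' @export
autoplot.sigmoid_fit <- function(object, ...) {
  grid <- tibble::tibble(t = seq(min(object$data$t) - 2,
                                 max(object$data$t) + 2, length.out = 200))
  grid$y <- predict(object, grid$t)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$t, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = grid, colour = "#0072B2", linewidth = 0.8) +
    ggplot2::labs(x = "leaf temperature (°C)", y = object$labels[["y"]]) +
    ggplot2::theme_minimal()
}

#' Plot a substrate-control regression
#'
#' Retained points with the fitted line; excluded (decoupled) temperatures
#' shown in red.
#'
#' @param object A `substrate_fit` from [fit_substrate_control()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot substrate_fit
#' @export
autoplot.substrate_fit <- function(object, ...) {
  lb <- object$labels
  used <- object$lm$model
  names(used) <- c("y", "x")
  exc <- object$excluded
  p <- ggplot2::ggplot(used, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(intercept = object$intercept, slope = object$slope,
                         colour = "#0072B2") +
    ggplot2::labs(x = lb[["x"]], y = lb[["y"]],
                  subtitle = sprintf("r2 = %.3f (T in {%s} excluded)",
                                     object$r2,
                                     paste(object$exclude_temps, collapse = ", "))) +
    ggplot2::theme_minimal()
  if (nrow(exc) > 0) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(x = exc[[lb[["x"]]]], y = exc[[lb[["y"]]]]),
      colour = "#D55E00", shape = 17, size = 2
    )
  }
  p
}

#' Temperature-response panel of group emissions
#'
#' Mean +/- SD of each VOC group's emission per treatment cell, by CO2
#' level, the diagnostic analog of a multi-panel group-burst figure.
#'
#' @param group_means Per-leaf group emission table (`t_leaf_c`, `co2`,
#'   `group`, `flux_nmol_m2_s`).
#' @return A ggplot object, faceted by group with free y scales.
#' @export
plot_group_response <- function(group_means) {
  cell <- group_means |>
    dplyr::summarise(mean = mean(.data$flux_nmol_m2_s),
                     sd = sd(.data$flux_nmol_m2_s),
                     .by = c("group", "t_leaf_c", "co2"))
  ggplot2::ggplot(cell, ggplot2::aes(x = .data$t_leaf_c, y = .data$mean,
                                     colour = factor(.data$co2))) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 1)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 1)) +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "leaf temperature (°C)",
                  y = expression(paste("emission (nmol ", m^-2, " ", s^-1, ")")),
                  colour = expression(paste(CO[2], " (µmol ", mol^-1, ")"))) +
    ggplot2::theme_minimal()
}
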