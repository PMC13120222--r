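#' Tidy a decay fit
#'
#' One row per estimated quantity, in the broom convention.
#'
#' @param x A `decay_fit` from [analyze_decay()].
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `unit`.
#' @method tidy decay_fit
#' @export
tidy.decay_fit <- function(x, ...) {
  r <- x$result
  tibble::tibble(
    term = c("t_off", "e_ss", "e_dark", "s_pool",
             "k_loglin", "k_slope", "k_ratio"),
    estimate = c(r$t_off, r$e_ss, r$e_dark, r$s_pool,
                 r$k_loglin, r$k_slope, r$k_ratio),
    unit = c("s", "nmol m-2 s-1", "nmol m-2 s-1", "nmol m-2",
             "s-1", "s-1", "s-1")
  )
}

#' Glance at a decay fit
#'
#' @inheritParams tidy.decay_fit
#' @return The one-row result tibble (`t_off`, `e_ss`, `e_dark`, `s_pool`,
#'   the three rate-constant estimates, `r2_loglin`, drift and baseline
#'   diagnostics, `flags`).
#' @method glance decay_fit
#' @export
glance.decay_fit <- function(x, ...) {
  x$result
}

#' Tidy a sigmoid temperature-response fit
#'
#' @param x A `sigmoid_fit` from [fit_sigmoid()].
#' @param ... Unused.
#' @return A tibble with `term` and `estimate` for the four logistic
#'   parameters.
#' @method tidy sigmoid_fit
#' @export
tidy.sigmoid_fit <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    term = c("y_min", "y_max", "t_mid", "scale"),
    estimate = c(cf$y_min, cf$y_max, cf$t_mid, cf$scale)
  )
}

#' @rdname tidy.sigmoid_fit
#' @method glance sigmoid_fit
#' @export
glance.sigmoid_fit <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    y_min = cf$y_min, y_max = cf$y_max, t_mid = cf$t_mid, scale = cf$scale,
    residual_sd = x$sigma, n = nrow(x$data),
    converged = x$converged, degenerate = x$degenerate
  )
}

#' Tidy a substrate-control regression
#'
#' @param x A `substrate_fit` from [fit_substrate_control()].
#' @param ... Unused.
#' @return A tibble with `term` (`intercept`, `slope`) and `estimate`.
#' @method tidy substrate_fit
#' @export
tidy.substrate_fit <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope)
  )
}

#' @rdname tidy.substrate_fit
#' @method glance substrate_fit
#' @export
glance.substrate_fit <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, r2 = x$r2,
    p_slope = x$p_slope, n_used = x$n_used,
    n_excluded = nrow(x$excluded),
    excluded_temps = paste(x$exclude_temps, collapse = ",")
  )
}
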