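#' Four-parameter logistic temperature-response fit
#'
#' Least-squares fit of the monotone saturating sigmoid
#' \eqn{y(T) = y_{min} + (y_{max} - y_{min}) / (1 + e^{-(T - T_{mid})/s})}
#' to per-leaf responses, by Levenberg-Marquardt with multi-start
#' initialization (several midpoint/scale starting points; the best
#' converged fit wins).  Degenerate data (flat response) are fitted with
#' `y_max ~ y_min` and flagged rather than rejected.
#'
#' @param data A data frame of per-leaf values.
#' @param temp,y Column names (strings) of temperature (degrees C) and
#'   response.
#' @return An object of class `sigmoid_fit` with [tidy()], [glance()],
#'   [predict()] and [autoplot()] methods.
#' @examples
#' d <- tibble::tibble(t = rep(c(25, 30, 35, 40), each = 6))
#' d$y <- logistic4(d$t, 1, 13, 36, 1.5)
#' fit_sigmoid(d, "t", "y")
#' @export
fit_sigmoid <- function(data, temp = "t_leaf_c", y = "value") {
  tt <- data[[temp]]
  yy <- data[[y]]
  ok <- complete.cases(tt, yy)
  tt <- tt[ok]; yy <- yy[ok]
  if (length(unique(tt)) < 4) {
    abort("sigmoid fit needs >= 4 distinct temperatures")
  }
  rng <- diff(range(yy))
  if (rng <= .Machine$double.eps * max(1, max(abs(yy)))) {
    # constant response: degenerate sigmoid
    fit <- list(y_min = mean(yy), y_max = mean(yy),
                t_mid = mean(range(tt)), scale = 1,
                sigma = sd(yy), converged = TRUE, degenerate = TRUE)
    return(new_sigmoid_fit(fit, tt, yy, temp, y))
  }
  starts <- tidyr::expand_grid(
    t_mid = stats::quantile(tt, c(0.35, 0.5, 0.65), names = FALSE),
    scale = c(0.5, 1.5, 4) * diff(range(tt)) / 8
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nlsLM(
        yy ~ logistic4(tt, y_min, y_max, t_mid, scale),
        start = list(y_min = min(yy), y_max = max(yy),
                     t_mid = starts$t_mid[i], scale = starts$scale[i]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(f)) {
      rss <- sum(stats::resid(f)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = f, rss = rss)
    }
  }
  if (is.null(best)) {
    abort("sigmoid fit failed to converge from any start")
  }
  cf <- as.list(coef(best$fit))
  # canonical orientation: y_max is the upper asymptote
  if (cf$y_max < cf$y_min) {
    cf <- list(y_min = cf$y_max, y_max = cf$y_min,
               t_mid = cf$t_mid, scale = -cf$scale)
  }
  t_ok <- cf$t_mid >= min(tt) - 10 && cf$t_mid <= max(tt) + 10
  fit <- c(cf, list(
    sigma = sqrt(best$rss / max(1, length(yy) - 4)),
    converged = isTRUE(best$fit$convInfo$isConv) && t_ok,
    degenerate = FALSE
  ))
  new_sigmoid_fit(fit, tt, yy, temp, y)
}

new_sigmoid_fit <- function(fit, tt, yy, temp, y) {
  structure(
    list(coefficients = fit[c("y_min", "y_max", "t_mid", "scale")],
         sigma = fit$sigma, converged = fit$converged,
         degenerate = fit$degenerate,
         data = tibble::tibble(t = tt, y = yy),
         labels = c(temp = temp, y = y)),
    class = "sigmoid_fit"
  )
}

#' @param object A `sigmoid_fit`.
#' @param newdata Optional data frame with the temperature column (or a
#'   numeric vector of temperatures).
#' @param ... Unused.
#' @rdname fit_sigmoid
#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  tt <- if (is.null(newdata)) {
    object$data$t
  } else if (is.numeric(newdata)) {
    newdata
  } else {
    newdata[[object$labels[["temp"]]]]
  }
  cf <- object$coefficients
  logistic4(tt, cf$y_min, cf$y_max, cf$t_mid, cf$scale)
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "<sigmoid_fit> y_min = %.4g, y_max = %.4g, t_mid = %.4g degC, scale = %.4g degC\n",
    cf$y_min, cf$y_max, cf$t_mid, cf$scale
  ))
  cat(sprintf("  residual SD = %.3g; converged: %s%s\n", x$sigma,
              x$converged, if (x$degenerate) " (degenerate: flat response)" else ""))
  invisible(x)
}

#' Substrate-control regression with temperature exclusion
#'
#' Ordinary least squares of an emission rate on a substrate-side driver
#' (DMADP pool size or apparent IspS rate constant), excluding a configurable
#' set of temperatures from the fit (default: the 40 degrees C cells, where
#' emission decouples from substrate control).  Excluded points are recorded
#' in the result, never silently dropped.
#'
#' @param data Per-leaf table.
#' @param x,y Column names (strings) of the driver and the emission rate.
#' @param temp Column name of leaf temperature.
#' @param exclude_temps Temperatures (degrees C) excluded from the fit.
#' @return An object of class `substrate_fit` with [tidy()] and [glance()]
#'   methods; fields include `slope`, `intercept`, `r2`, `n_used` and the
#'   `excluded` rows.
#' @export
fit_substrate_control <- function(data, x, y, temp = "t_leaf_c",
                                  exclude_temps = 40) {
  keep <- !(data[[temp]] %in% exclude_temps)
  used <- data[keep & complete.cases(data[[x]], data[[y]]), , drop = FALSE]
  if (nrow(used) < 3) abort("fewer than 3 points remain after exclusion")
  if (length(unique(used[[x]])) < 2) {
    abort("driver has a single value after exclusion; slope is not identifiable")
  }
  fit <- lm(stats::reformulate(x, y), data = used)
  sm <- suppressWarnings(summary(fit))   # exact proportionality warns in summary.lm
  structure(
    list(
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
      r2 = sm$r.squared, n_used = nrow(used),
      p_slope = sm$coefficients[2, 4],
      excluded = data[!keep, , drop = FALSE],
      exclude_temps = exclude_temps,
      labels = c(x = x, y = y, temp = temp),
      lm = fit
    ),
    class = "substrate_fit"
  )
}

#' @export
print.substrate_fit <- function(x, ...) {
  cat(sprintf(
    "<substrate_fit> %s = %.4g + %.4g * %s  (r2 = %.4f, n = %d; %d point(s) at T in {%s} excluded)\n",
    x$labels[["y"]], x$intercept, x$slope, x$labels[["x"]], x$r2, x$n_used,
    nrow(x$excluded), paste(x$exclude_temps, collapse = ", ")
  ))
  invisible(x)
}

p_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}

#' Per-temperature comparison of CO2 treatments
#'
#' Independent two-tailed Student's t-test (pooled variance) between the two
#' CO2 levels at each temperature, computed from the textbook statistic
#' \eqn{t = (\bar x_1 - \bar x_2) / (s_p \sqrt{1/n_1 + 1/n_2})} with
#' \eqn{df = n_1 + n_2 - 2}.  A Welch variant is available behind
#' `var_equal = FALSE` and is never substituted silently.  Temperatures with
#' fewer than two leaves in either cell are reported with `skipped = TRUE`
#' rather than dropped.  No multiple-testing correction is applied; the
#' number of tests performed is attached as attribute `n_tests`.
#'
#' @param data Per-leaf table.
#' @param value Column name (string) of the per-leaf statistic to compare.
#' @param temp,co2 Column names of temperature and CO2 level.
#' @param var_equal Pooled-variance (Student's) test when `TRUE` (default).
#' @return A tibble, one row per temperature: cell means and SDs, `t_stat`,
#'   `df`, `p_value`, `stars`, `skipped`.
#' @export
compare_treatments <- function(data, value, temp = "t_leaf_c", co2 = "co2",
                               var_equal = TRUE) {
  lev <- sort(unique(data[[co2]]))
  if (length(lev) != 2) abort("compare_treatments expects exactly two CO2 levels")
  out <- data |>
    dplyr::rename(.value = dplyr::all_of(value)) |>
    dplyr::summarise(
      n = sum(is.finite(.data$.value)),
      mean = mean(.data$.value, na.rm = TRUE),
      sd = sd(.data$.value, na.rm = TRUE),
      .by = dplyr::all_of(c(temp, co2))
    ) |>
    tidyr::pivot_wider(
      names_from = dplyr::all_of(co2),
      values_from = c("n", "mean", "sd"),
      names_glue = "{.value}_{co2}"
    )
  n1 <- out[[paste0("n_", lev[1])]]; n2 <- out[[paste0("n_", lev[2])]]
  m1 <- out[[paste0("mean_", lev[1])]]; m2 <- out[[paste0("mean_", lev[2])]]
  s1 <- out[[paste0("sd_", lev[1])]]; s2 <- out[[paste0("sd_", lev[2])]]
  skipped <- is.na(n1) | is.na(n2) | n1 < 2 | n2 < 2
  if (var_equal) {
    sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  } else {
    v1 <- s1^2 / n1; v2 <- s2^2 / n2
    se <- sqrt(v1 + v2)
    df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  }
  t_stat <- (m1 - m2) / se
  t_stat[se == 0] <- 0                       # identical cells: no evidence
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  res <- out |>
    dplyr::mutate(
      t_stat = ifelse(skipped, NA_real_, t_stat),
      df = ifelse(skipped, NA_real_, df),
      p_value = ifelse(skipped, NA_real_, p),
      stars = p_stars(.data$p_value),
      skipped = skipped
    )
  attr(res, "n_tests") <- sum(!skipped)
  res
}

#' Treatment-level report tables
#'
#' Assembles the figure-analog tidy tables for a full experiment:
#' \describe{
#'   \item{`assimilation`}{A_net and isoprene steady-state emission per
#'     treatment cell (temperature response of gas exchange).}
#'   \item{`dmadp_pool`}{DMADP pool size per treatment cell with sigmoid fit
#'     parameters per CO2 level.}
#'   \item{`substrate_control`}{emission vs pool and emission vs rate
#'     constant regressions with the excluded-temperature sets.}
#'   \item{`group_response`}{per-group mean emission per treatment cell.}
#'   \item{`ttests`}{per-temperature CO2 comparisons for each reported
#'     quantity.}
#'   \item{`sigmoid_params`}{all sigmoid fit parameters in long form.}
#' }
#'
#' @param decays Per-leaf decay results (from [analyze_experiment()]),
#'   including `t_leaf_c`, `co2`, `e_ss`, `s_pool`, `k_loglin` and `flags`.
#' @param group_means Optional per-leaf group emission table with columns
#'   `t_leaf_c`, `co2`, `replicate`, `group`, `flux_nmol_m2_s`.
#' @param a_net Optional per-leaf table with `t_leaf_c`, `co2`, `a_net`.
#' @param exclude_temps Temperatures excluded from substrate-control fits.
#' @param drop_flagged Exclude decays flagged `baseline-not-reached` from
#'   the statistics (default TRUE).
#' @return A list of tibbles as described above.
#' @export
build_report <- function(decays, group_means = NULL, a_net = NULL,
                         exclude_temps = 40, drop_flagged = TRUE) {
  if (!"error" %in% names(decays)) decays$error <- NA_character_
  d <- decays[is.na(decays$error), , drop = FALSE]
  n_failed <- sum(!is.na(decays$error))
  n_flagged <- 0L
  if (drop_flagged && "flags" %in% names(d)) {
    flagged <- grepl("baseline-not-reached", d$flags)
    n_flagged <- sum(flagged)
    d <- d[!flagged, , drop = FALSE]
  }
  if (nrow(d) == 0) abort("no usable decay results")

  cell_stats <- function(df, col) {
    df |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data[[col]]),
        sd = sd(.data[[col]]),
        .by = c("t_leaf_c", "co2")
      ) |>
      dplyr::arrange(.data$t_leaf_c, .data$co2)
  }

  sig_by_co2 <- function(df, col) {
    purrr::map(split(df, df$co2), function(dd) {
      tryCatch(fit_sigmoid(dd, "t_leaf_c", col), error = function(e) NULL)
    })
  }
  sig_rows <- function(fits, quantity) {
    purrr::list_rbind(purrr::imap(fits, function(f, co2) {
      if (is.null(f)) return(tibble::tibble())
      cf <- f$coefficients
      tibble::tibble(
        quantity = quantity, co2 = as.numeric(co2),
        y_min = cf$y_min, y_max = cf$y_max, t_mid = cf$t_mid,
        scale = cf$scale, residual_sd = f$sigma, converged = f$converged
      )
    }))
  }

  fig1 <- cell_stats(d, "e_ss") |>
    dplyr::rename(isoprene_mean = "mean", isoprene_sd = "sd")
  if (!is.null(a_net)) {
    an <- a_net |>
      dplyr::summarise(a_net_mean = mean(.data$a_net),
                       a_net_sd = sd(.data$a_net),
                       .by = c("t_leaf_c", "co2"))
    fig1 <- dplyr::left_join(fig1, an, by = c("t_leaf_c", "co2"))
  }

  fig2 <- cell_stats(d, "s_pool") |>
    dplyr::rename(s_pool_mean = "mean", s_pool_sd = "sd")

  fits_pool <- sig_by_co2(d, "s_pool")
  fits_iso <- sig_by_co2(d, "e_ss")

  sub_glance <- function(driver) {
    f <- tryCatch(
      fit_substrate_control(d, driver, "e_ss", exclude_temps = exclude_temps),
      error = function(e) NULL
    )
    if (is.null(f)) return(tibble::tibble())
    dplyr::mutate(glance(f), driver = driver, .before = 1)
  }
  fig3 <- dplyr::bind_rows(sub_glance("s_pool"), sub_glance("k_loglin"))

  safe_compare <- function(df, col, quantity) {
    out <- tryCatch(compare_treatments(df, col), error = function(e) NULL)
    if (is.null(out)) {
      out <- tibble::tibble()
      attr(out, "n_tests") <- 0L
      return(out)
    }
    dplyr::mutate(out, quantity = quantity, .before = 1)
  }
  fig4 <- NULL
  ttests <- list(
    dmadp_pool = safe_compare(d, "s_pool", "s_pool"),
    isoprene = safe_compare(d, "e_ss", "e_ss")
  )
  sig_params <- dplyr::bind_rows(
    sig_rows(fits_pool, "s_pool"),
    sig_rows(fits_iso, "e_ss")
  )

  if (!is.null(group_means)) {
    fig4 <- group_means |>
      dplyr::summarise(
        n = dplyr::n(),
        mean = mean(.data$flux_nmol_m2_s),
        sd = sd(.data$flux_nmol_m2_s),
        .by = c("group", "t_leaf_c", "co2")
      ) |>
      dplyr::arrange(.data$group, .data$t_leaf_c, .data$co2)
    gt <- purrr::list_rbind(purrr::map(
      split(group_means, group_means$group),
      function(gd) safe_compare(gd, "flux_nmol_m2_s",
                                paste0("flux_", gd$group[1]))
    ))
    ttests$groups <- gt
    sig_params <- dplyr::bind_rows(
      sig_params,
      purrr::list_rbind(purrr::map(
        split(group_means, group_means$group),
        function(gd) sig_rows(sig_by_co2(gd, "flux_nmol_m2_s"),
                              paste0("flux_", gd$group[1]))
      ))
    )
  }

  ttab <- purrr::list_rbind(ttests)
  attr(ttab, "n_tests") <- sum(purrr::map_int(ttests, ~ attr(.x, "n_tests") %||% 0L))
  list(
    assimilation = fig1,
    dmadp_pool = fig2,
    substrate_control = fig3,
    group_response = fig4,
    ttests = ttab,
    sigmoid_params = sig_params,
    n_excluded_flagged = n_flagged,
    n_failed_traces = n_failed
  )
}
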