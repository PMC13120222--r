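#' Analysis windows for the post-illumination decay
#'
#' @param ss_window Duration before the dark transition used to estimate
#'   steady-state emission (s).
#' @param initial_window Duration after the transition used for rate-constant
#'   fitting (s).  20 s covers at most ~1.5 mean lifetimes at the highest
#'   physiological rate constants while giving usable slope precision at
#'   1 Hz for the slow (cool-leaf) decays.
#' @param baseline_slope_tol Stability criterion for the dark baseline:
#'   maximum fitted |slope| in the baseline window, as a fraction of
#'   steady-state emission per second.
#' @param baseline_stable Minimum stable duration of the baseline window (s).
#' @param drift_tol Steady-state drift criterion: maximum |slope| over the
#'   steady-state window as a fraction of the mean per second before the
#'   drift flag is raised.
#' @return A list of class `decay_windows`.
#' @export
decay_windows <- function(ss_window = 60, initial_window = 20,
                          baseline_slope_tol = 0.005, baseline_stable = 30,
                          drift_tol = 0.001) {
  stopifnot(ss_window >= 2, initial_window >= 2, baseline_stable >= 2,
            baseline_slope_tol > 0, drift_tol > 0)
  structure(
    list(ss_window = ss_window, initial_window = initial_window,
         baseline_slope_tol = baseline_slope_tol,
         baseline_stable = baseline_stable, drift_tol = drift_tol),
    class = "decay_windows"
  )
}

#' Detect the light-to-dark transition
#'
#' Returns the time of the first sample where PPFD falls below 1% of its
#' light-phase median.  If the series has no `ppfd` column the fallback is
#' the largest single-step drop in the flux (or isoprene channel) series.
#'
#' @param data A tibble with `time_s` and either `ppfd` or `flux` /
#'   `chi_isoprene`.
#' @return `t_off` (s), the first dark sample time.
#' @export
detect_transition <- function(data) {
  if ("ppfd" %in% names(data) && !all(is.na(data$ppfd))) {
    p <- data$ppfd
    lit <- p > 0.05 * max(p, na.rm = TRUE)
    if (!any(lit)) abort("no dark transition in trace: PPFD never above noise")
    med <- median(p[lit], na.rm = TRUE)
    dark <- which(p < 0.01 * med)
    if (length(dark) == 0) abort("no dark transition in trace: PPFD never drops")
    if (dark[1] == 1) abort("no dark transition in trace: trace starts dark")
    return(data$time_s[dark[1]])
  }
  sig_col <- intersect(c("flux", "chi_isoprene"), names(data))[1]
  if (is.na(sig_col)) abort("trace has neither a ppfd column nor a flux/chi_isoprene fallback")
  s <- data[[sig_col]]
  n <- length(s)
  m <- 30L                              # trailing window estimating the lit level
  w <- 3L                               # forward windows tested for departure
  if (n < m + 2 * w + 1) abort("trace too short for change-point fallback")
  for (j in (m + 1):(n - 2 * w + 1)) {
    trail <- s[(j - m):(j - 1)]
    lit <- mean(trail)
    # noise scale from the trailing (still lit) window only
    sigma <- max(sd(diff(trail)) / sqrt(2), .Machine$double.eps)
    thresh <- lit - 4 * sigma / sqrt(w)
    # sequential test: two consecutive non-overlapping forward means depart
    # below the lit level, so a lone noise excursion cannot trigger
    if (mean(s[j:(j + w - 1)]) < thresh &&
        mean(s[(j + w):(j + 2 * w - 1)]) < thresh) {
      return(data$time_s[j])
    }
  }
  abort("no dark transition in trace: signal never departs from the lit level")
}

ls_slope <- function(t, y) {
  tc <- t - mean(t)
  sum(tc * (y - mean(y))) / sum(tc^2)
}

#' Steady-state emission before darkening
#'
#' Mean flux over the `ss_window` seconds preceding the dark transition,
#' with a linear drift check over the same window.
#'
#' @param data Tibble with `time_s` and `flux`.
#' @param t_off Dark-transition time (s), see [detect_transition()].
#' @param windows A [decay_windows()].
#' @return One-row tibble: `e_ss`, `ss_drift` (fitted slope / e_ss, per s),
#'   `drift_flag`.
#' @export
estimate_steady_state <- function(data, t_off, windows = decay_windows()) {
  sel <- data$time_s >= t_off - windows$ss_window & data$time_s < t_off
  if (sum(sel) < 2) abort("steady-state window does not fit before t_off")
  e_ss <- mean(data$flux[sel])
  slope <- ls_slope(data$time_s[sel], data$flux[sel])
  drift <- if (abs(e_ss) > 0) slope / e_ss else slope
  tibble::tibble(e_ss = e_ss, ss_drift = drift,
                 drift_flag = abs(drift) > windows$drift_tol)
}

#' Dark baseline of the decay tail
#'
#' Estimates the residual dark emission from the terminal window of the dark
#' tail (the most exhausted part of the decay): the mean over the last
#' `baseline_stable` seconds, accepted when the fitted |slope| over that
#' window is below `baseline_slope_tol` x steady-state emission per second.
#' When the terminal window is still decaying the mean is returned anyway
#' with `baseline_not_reached = TRUE`.
#'
#' @inheritParams estimate_steady_state
#' @param e_ss Steady-state emission used to scale the slope criterion;
#'   estimated from the trace when `NULL`.
#' @return One-row tibble: `e_dark`, `baseline_start_s`,
#'   `baseline_not_reached`.
#' @export
estimate_dark_baseline <- function(data, t_off, windows = decay_windows(),
                                   e_ss = NULL) {
  tail_sel <- data$time_s >= t_off
  if (sum(tail_sel) < 2) abort("trace does not extend beyond t_off")
  if (is.null(e_ss)) e_ss <- estimate_steady_state(data, t_off, windows)$e_ss
  t_end <- max(data$time_s)
  start <- max(t_off, t_end - windows$baseline_stable)
  sel <- data$time_s >= start
  if (sum(sel) < 2) sel <- tail_sel
  slope <- ls_slope(data$time_s[sel], data$flux[sel])
  stable <- abs(slope) <= windows$baseline_slope_tol * max(abs(e_ss), 1e-12)
  tibble::tibble(
    e_dark = mean(data$flux[sel]),
    baseline_start_s = min(data$time_s[sel]),
    baseline_not_reached = !stable
  )
}

#' DMADP pool size by integrating the decay curve
#'
#' Trapezoidal integral of the baseline-corrected emission excess
#' \eqn{E(t) - E_{dark}} from the dark transition to the start of the
#' accepted baseline window, on the native sampling grid.  Negative
#' excursions are retained (they cancel noise in expectation); a negative
#' total integral signals baseline overestimation and is rejected.
#'
#' @inheritParams estimate_steady_state
#' @param e_dark Dark baseline (nmol m-2 s-1).
#' @param t_end Upper integration limit (s); defaults to the trace end, and
#'   is normally the baseline window start from [estimate_dark_baseline()].
#' @return `s_pool` (nmol m-2).
#' @export
integrate_pool <- function(data, t_off, e_dark, t_end = NULL) {
  t_end <- t_end %||% max(data$time_s)
  sel <- data$time_s >= t_off & data$time_s <= t_end
  if (sum(sel) < 2) abort("integration window contains fewer than 2 samples")
  t <- data$time_s[sel]
  y <- data$flux[sel] - e_dark
  s_pool <- sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
  if (s_pool < 0) {
    abort(sprintf("negative decay integral (%.3g): dark baseline overestimated", s_pool))
  }
  s_pool
}

# Finite-window-corrected initial-rate estimator: find k such that an exact
# exponential sampled on the same grid reproduces the observed ratio of
# least-squares slope to mean excess.  Exact for noise-free first-order decay
# regardless of window length.
k_from_slope_ratio <- function(t, ratio) {
  if (!is.finite(ratio) || ratio <= 0) return(NA_real_)
  rho <- function(k) {
    e <- exp(-k * (t - t[1]))
    -ls_slope(t, e) / mean(e)
  }
  upper <- 10
  if (rho(upper) < ratio) return(ratio)   # window too short to correct; raw ratio
  uniroot(function(k) rho(k) - ratio, c(1e-9, upper), tol = 1e-12)$root
}

#' Apparent IspS rate constant from the initial decay
#'
#' Two estimators over the `initial_window` after the transition:
#' \describe{
#'   \item{`k_loglin`}{minus the least-squares slope of
#'     \eqn{\ln(E - E_{dark})} versus time (log-linear fit), with its r2.}
#'   \item{`k_slope`}{the initial-rate estimator: the least-squares slope of
#'     E versus time normalized by the window-mean excess, with the
#'     finite-window correction that makes it exact for first-order decay
#'     sampled on the same grid.}
#' }
#'
#' @inheritParams estimate_steady_state
#' @param e_ss Steady-state emission (nmol m-2 s-1).
#' @param e_dark Dark baseline (nmol m-2 s-1).
#' @return One-row tibble: `k_slope`, `k_loglin`, `r2_loglin`, `n_fit`.
#' @export
fit_rate_constant <- function(data, t_off, e_ss, e_dark,
                              windows = decay_windows()) {
  sel <- data$time_s >= t_off & data$time_s < t_off + windows$initial_window
  t <- data$time_s[sel]
  excess <- data$flux[sel] - e_dark
  pos <- excess > 0
  if (sum(pos) < 3) abort("no decay signal: emission does not exceed the dark baseline")
  # log-linear estimator
  fit <- lm(log(excess[pos]) ~ t[pos])
  k_loglin <- -unname(coef(fit)[2])
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn in summary.lm
  # corrected initial-rate estimator on the full window
  ratio <- -ls_slope(t, excess) / mean(excess)
  k_slope <- k_from_slope_ratio(t, ratio)
  tibble::tibble(k_slope = k_slope, k_loglin = k_loglin,
                 r2_loglin = r2, n_fit = length(t))
}

#' Full post-illumination decay analysis
#'
#' Runs the complete inference chain on one isoprene flux series: transition
#' detection, steady-state and dark-baseline estimation, decay-curve
#' integration (DMADP pool) and rate-constant fitting, plus the consistency
#' estimator \eqn{k_{ratio} = (E_{ss} - E_{dark}) / S_{pool}} implied by the
#' first-order identity \eqn{S \, k = E_{ss} - E_{dark}}.  Any stage failure
#' is re-signalled with the stage name.
#'
#' @param data A tibble with `time_s`, `flux` and (preferably) `ppfd`, e.g.
#'   from [isoprene_flux()].
#' @param windows A [decay_windows()].
#' @return An object of class `decay_fit`; see [glance.decay_fit()] for the
#'   one-row summary and [tidy.decay_fit()] for the per-parameter table.
#' @examples
#' p <- kinetic_params(s0 = 300, f_supply = 15, k_isps = 0.05)
#' dyn <- simulate_pool_dynamics(p, light_protocol(120, 300))
#' fit <- analyze_decay(dplyr::transmute(dyn, time_s, ppfd, flux = emission))
#' glance(fit)
#' @export
analyze_decay <- function(data, windows = decay_windows()) {
  req <- c("time_s", "flux")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) {
    abort(paste0("decay input is missing column(s): ", paste(miss, collapse = ", ")))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage %s: %s", name, conditionMessage(e)))
    })
  }
  t_off <- stage("detect_transition", detect_transition(data))
  ss <- stage("estimate_steady_state", estimate_steady_state(data, t_off, windows))
  bl <- stage("estimate_dark_baseline",
              estimate_dark_baseline(data, t_off, windows, e_ss = ss$e_ss))
  s_pool <- stage("integrate_pool",
                  integrate_pool(data, t_off, bl$e_dark,
                                 t_end = bl$baseline_start_s))
  kfit <- stage("fit_rate_constant",
                fit_rate_constant(data, t_off, ss$e_ss, bl$e_dark, windows))
  k_ratio <- if (s_pool > 0) (ss$e_ss - bl$e_dark) / s_pool else NA_real_
  flags <- c(
    if (ss$drift_flag) "steady-state-drift",
    if (bl$baseline_not_reached) c("baseline-not-reached", "truncated-integral")
  )
  structure(
    list(
      result = tibble::tibble(
        t_off = t_off, e_ss = ss$e_ss, e_dark = bl$e_dark,
        s_pool = s_pool, k_loglin = kfit$k_loglin, k_slope = kfit$k_slope,
        k_ratio = k_ratio, r2_loglin = kfit$r2_loglin,
        ss_drift = ss$ss_drift, baseline_start_s = bl$baseline_start_s,
        flags = paste(flags, collapse = ";")
      ),
      data = data, windows = windows
    ),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  r <- x$result
  cat("<decay_fit>\n")
  cat(sprintf("  t_off = %.0f s, E_ss = %.3g, E_dark = %.3g nmol m-2 s-1\n",
              r$t_off, r$e_ss, r$e_dark))
  cat(sprintf("  S_pool = %.4g nmol m-2;  k: loglin %.4g, slope %.4g, ratio %.4g s-1 (r2 = %.3f)\n",
              r$s_pool, r$k_loglin, r$k_slope, r$k_ratio, r$r2_loglin))
  if (nzchar(r$flags)) cat("  flags:", r$flags, "\n")
  invisible(x)
}

#' Decay analysis of every trace in a simulated or measured experiment
#'
#' Maps [analyze_decay()] over the traces of an experiment (as produced by
#' [generate_experiment()] or assembled from [read_trace()] calls),
#' computing each trace's blank-corrected isoprene flux first.  Failures are
#' isolated: a trace whose analysis errors contributes a row with the error
#' message in `error` instead of stopping the run.
#'
#' @param traces Tibble with design columns (`t_leaf_c`, `co2`, `replicate`,
#'   `trace_id`) and a `trace` list-column.
#' @param geom A [chamber_geometry()].
#' @param registry Channel registry.
#' @param blanks Optional tibble with `t_leaf_c`, `co2` and a `blank`
#'   list-column of matched empty-chamber traces.
#' @param windows A [decay_windows()].
#' @param dynamic Use the dynamic (storage-term) mass balance.
#' @return A tibble: design columns, the [glance.decay_fit()] columns and
#'   `error` (NA on success).
#' @export
analyze_experiment <- function(traces, geom = chamber_geometry(),
                               registry = default_channel_registry(),
                               blanks = NULL, windows = decay_windows(),
                               dynamic = FALSE) {
  rows <- purrr::map(seq_len(nrow(traces)), function(i) {
    meta <- dplyr::select(traces[i, ], dplyr::any_of(
      c("trace_id", "t_leaf_c", "co2", "replicate")
    ))
    res <- tryCatch({
      blank <- NULL
      if (!is.null(blanks)) {
        j <- which(blanks$t_leaf_c == traces$t_leaf_c[i] &
                     blanks$co2 == traces$co2[i])
        if (length(j) >= 1) blank <- blanks$blank[[j[1]]]
      }
      fx <- isoprene_flux(traces$trace[[i]], geom, registry,
                          blank = blank, dynamic = dynamic)
      fit <- analyze_decay(fx, windows)
      dplyr::mutate(fit$result, error = NA_character_)
    }, error = function(e) {
      tibble::tibble(error = conditionMessage(e))
    })
    dplyr::bind_cols(meta, res)
  })
  purrr::list_rbind(rows)
}
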