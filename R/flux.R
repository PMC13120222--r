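#' Leaf emission flux from the cuvette mass balance
#'
#' Steady-state mass balance of a flow-through cuvette:
#' \eqn{E = Q (\chi_{out} - \chi_{in}) / A} with molar flow Q and leaf area
#' A, giving E in nmol m-2 s-1 for mixing ratios in nmol mol-1.  With
#' `dynamic = TRUE` the chamber storage term \eqn{(n/A) \, d\chi/dt} is
#' added (central differences on the native grid), which removes the
#' washout lag during fast transients such as the post-illumination decay.
#'
#' @param chi_out Outlet mixing ratio series (nmol mol-1).
#' @param chi_in Inlet mixing ratio (scalar or series, nmol mol-1).
#' @param geom A [chamber_geometry()].
#' @param time_s Sample times (s); required for `dynamic = TRUE`.
#' @param dynamic Include the chamber storage term (uses `geom$n_chamber`).
#' @return Emission flux (nmol m-2 s-1), same length as `chi_out`.
#' @examples
#' g <- chamber_geometry(q_flow = 500, a_leaf = 6e-4)
#' flux_from_mixing_ratio(1, 0, g)  # 0.8333
#' @export
flux_from_mixing_ratio <- function(chi_out, chi_in = 0, geom = chamber_geometry(),
                                   time_s = NULL, dynamic = FALSE) {
  stopifnot(inherits(geom, "chamber_geometry"))
  if (length(chi_in) > 1 && length(chi_in) != length(chi_out)) {
    abort("chi_in and chi_out are on different time bases (lengths differ)")
  }
  q_mol <- geom$q_flow * 1e-6
  flux <- q_mol * (chi_out - chi_in) / geom$a_leaf
  if (dynamic && geom$n_chamber > 0) {
    if (is.null(time_s)) abort("time_s is required for the dynamic storage term")
    if (length(time_s) != length(chi_out)) {
      abort("time_s and chi_out are on different time bases (lengths differ)")
    }
    dchi <- numeric(length(chi_out))
    n <- length(chi_out)
    if (n >= 2) {
      dchi[1] <- (chi_out[2] - chi_out[1]) / (time_s[2] - time_s[1])
      dchi[n] <- (chi_out[n] - chi_out[n - 1]) / (time_s[n] - time_s[n - 1])
      if (n >= 3) {
        i <- 2:(n - 1)
        dchi[i] <- (chi_out[i + 1] - chi_out[i - 1]) / (time_s[i + 1] - time_s[i - 1])
      }
    }
    flux <- flux + (geom$n_chamber * 1e-6 / geom$a_leaf) * dchi
  }
  flux
}

#' Empty-chamber blank correction
#'
#' Subtracts the empty-chamber signal from a sample series measured under
#' matched environmental conditions.  Because blanks and samples are not
#' acquired synchronously, the default subtracts the time-mean of the blank
#' window; `mode = "pointwise"` subtracts sample-by-sample (requires equal
#' length).  Negative corrected values are preserved, never clipped.
#'
#' @param sample Numeric sample series (mixing ratio or flux units).
#' @param blank Numeric blank series in the same units.
#' @param mode `"mean"` (default) or `"pointwise"`.
#' @return Corrected numeric series with attribute `blank_level` (the
#'   subtracted level for `"mean"` mode).
#' @export
blank_correct <- function(sample, blank, mode = c("mean", "pointwise")) {
  mode <- match.arg(mode)
  if (length(blank) == 0 || all(is.na(blank))) {
    abort("no blank available for this treatment cell")
  }
  if (mode == "mean") {
    lev <- mean(blank, na.rm = TRUE)
    out <- sample - lev
    attr(out, "blank_level") <- lev
  } else {
    if (length(blank) != length(sample)) {
      abort("pointwise blank correction requires blank and sample of equal length")
    }
    out <- sample - blank
  }
  out
}

#' Per-compound flux table for one trace
#'
#' Pivots a trace's `chi_<compound>` channels to long form, applies the
#' cuvette mass balance per channel and (optionally) blank-corrects each
#' channel against the mean of the matched empty-chamber blank.  Channels
#' not present in the registry are kept with `group = NA`.
#'
#' @param trace A trace tibble (see [sim_trace()] / [read_trace()]).
#' @param geom A [chamber_geometry()]; `q_flow` is taken from the trace's
#'   `q_flow_umol_s` column when present.
#' @param registry Channel registry.
#' @param blank Optional matched blank trace tibble (same channel columns).
#' @param dynamic Include the chamber storage term (see
#'   [flux_from_mixing_ratio()]).
#' @param trace_id Identifier copied into the output.
#' @return A tidy tibble: `trace_id, time_s, compound, group,
#'   flux_nmol_m2_s, blank_corrected, negative`.
#' @export
compute_fluxes <- function(trace, geom = chamber_geometry(),
                           registry = default_channel_registry(),
                           blank = NULL, dynamic = FALSE,
                           trace_id = "trace") {
  chan_cols <- grep("^chi_", names(trace), value = TRUE)
  if (length(chan_cols) == 0) abort("trace has no chi_<compound> channel columns")
  q <- if ("q_flow_umol_s" %in% names(trace)) trace$q_flow_umol_s[1] else geom$q_flow
  g <- chamber_geometry(q, geom$a_leaf, geom$n_chamber, geom$chi_in)
  out <- purrr::map(chan_cols, function(col) {
    cmp <- sub("^chi_", "", col)
    chi <- trace[[col]]
    corrected <- FALSE
    if (!is.null(blank)) {
      if (!col %in% names(blank)) {
        abort(sprintf("blank trace has no channel column '%s'", col))
      }
      chi <- blank_correct(chi, blank[[col]], mode = "mean")
      corrected <- TRUE
    }
    flux <- flux_from_mixing_ratio(as.numeric(chi),
                                   chi_in = if (corrected) 0 else g$chi_in,
                                   geom = g, time_s = trace$time_s,
                                   dynamic = dynamic)
    grp <- registry$group[match(cmp, registry$compound)]
    tibble::tibble(
      trace_id = trace_id, time_s = trace$time_s, compound = cmp,
      group = grp, flux_nmol_m2_s = flux,
      blank_corrected = corrected, negative = flux < 0
    )
  })
  purrr::list_rbind(out)
}

#' Aggregate compound fluxes into biosynthetic groups
#'
#' Sums member-compound fluxes at each time point into the six VOC groups.
#' Every compound must be present in the registry; aggregation conserves
#' total flux (sum over groups equals sum over compounds).
#'
#' @param flux_df Long flux table as from [compute_fluxes()].
#' @param registry Channel registry.
#' @return A tibble `trace_id, time_s, group, flux_nmol_m2_s, n_compounds`.
#' @export
aggregate_groups <- function(flux_df, registry = default_channel_registry()) {
  unknown <- setdiff(unique(flux_df$compound), registry$compound)
  if (length(unknown) > 0) {
    abort(paste0("compound(s) absent from registry: ",
                 paste(unknown, collapse = ", ")))
  }
  flux_df |>
    dplyr::mutate(group = registry$group[match(.data$compound, registry$compound)]) |>
    dplyr::summarise(
      flux_nmol_m2_s = sum(.data$flux_nmol_m2_s),
      n_compounds = dplyr::n(),
      .by = c("trace_id", "time_s", "group")
    )
}

#' Isoprene flux series of a trace
#'
#' Convenience extractor: the blank-corrected (when a blank is supplied)
#' isoprene emission flux with the trace's time base and PPFD, the input the
#' decay analysis consumes.
#'
#' @inheritParams compute_fluxes
#' @return A tibble `time_s, ppfd, flux`.
#' @export
isoprene_flux <- function(trace, geom = chamber_geometry(),
                          registry = default_channel_registry(),
                          blank = NULL, dynamic = FALSE) {
  fx <- compute_fluxes(trace, geom, registry, blank = blank,
                       dynamic = dynamic)
  iso <- dplyr::filter(fx, .data$compound == "isoprene")
  if (nrow(iso) == 0) abort("trace has no isoprene channel (chi_isoprene)")
  tibble::tibble(time_s = iso$time_s,
                 ppfd = if ("ppfd" %in% names(trace)) trace$ppfd else NULL,
                 flux = iso$flux_nmol_m2_s)
}
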