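#' Drift-tube operating conditions and reduced electric field
#'
#' In PTR-MS the ion chemistry is controlled by the reduced electric field
#' E/N in the drift tube, expressed in Townsend (1 Td = 1e-17 V cm2).  With
#' drift voltage U over tube length L and buffer-gas number density
#' N = p / (kB T), the reduced field is (U/L) / N.
#'
#' `drift_conditions()` builds a validated condition record;
#' `reduced_field()` computes E/N from it.  E/N is always recomputed from
#' the primitive quantities, never stored.
#'
#' @param u_drift Drift voltage (V).
#' @param p_drift Drift pressure (mbar).
#' @param t_drift Drift temperature (degrees C).
#' @param l_drift Drift-tube length (cm); an instrument constant, default
#'   9.3 cm for the instrument class the package targets.
#' @return `drift_conditions()` returns a list of class `drift_conditions`;
#'   `reduced_field()` returns E/N in Td.
#' @examples
#' reduced_field(drift_conditions(600, 2.5, 60))  # ~118.7 Td
#' @export
drift_conditions <- function(u_drift, p_drift, t_drift, l_drift = 9.3) {
  vals <- c(u_drift = u_drift, p_drift = p_drift,
            t_drift = t_drift, l_drift = l_drift)
  if (any(!is.finite(vals))) {
    abort(paste0("non-finite drift condition: ",
                 paste(names(vals)[!is.finite(vals)], collapse = ", ")))
  }
  if (u_drift < 0) abort("u_drift must be >= 0")
  if (p_drift <= 0) abort("p_drift must be > 0")
  if (l_drift <= 0) abort("l_drift must be > 0")
  if (t_drift <= -273.15) abort("t_drift must be above absolute zero")
  structure(as.list(vals), class = "drift_conditions")
}

#' @param dc A `drift_conditions` object.
#' @param round_to Round the result to the nearest multiple of this value;
#'   `NULL` (default) returns the unrounded field.  Instrument settings are
#'   conventionally quoted to the nearest ten Td.
#' @rdname drift_conditions
#' @export
reduced_field <- function(dc, round_to = NULL) {
  stopifnot(inherits(dc, "drift_conditions"))
  kB <- 1.380649e-23                                   # J/K
  n_cm3 <- (dc$p_drift * 100) / (kB * (dc$t_drift + 273.15)) * 1e-6
  en_td <- (dc$u_drift / dc$l_drift) / n_cm3 / 1e-17
  if (!is.null(round_to)) en_td <- round(en_td / round_to) * round_to
  en_td
}

#' @export
print.drift_conditions <- function(x, ...) {
  cat(sprintf(
    "<drift_conditions> U = %g V, p = %g mbar, T = %g degC, L = %g cm  (E/N = %.1f Td)\n",
    x$u_drift, x$p_drift, x$t_drift, x$l_drift, reduced_field(x)
  ))
  invisible(x)
}
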