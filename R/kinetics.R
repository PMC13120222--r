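#' Isoprene precursor kinetic parameters
#'
#' Single-pool first-order model of chloroplastic isoprene biosynthesis: the
#' DMADP pool S (nmol m-2) is supplied by the MEP pathway at rate
#' `f_supply` while light is on and drained by isoprene synthase with
#' first-order rate constant `k_isps`, so
#' \deqn{dS/dt = F \cdot L(t) - k S, \qquad I(t) = k S(t) + E_{floor},}
#' where L(t) is 1 in the light and 0 in the dark and I is the isoprene
#' emission flux (nmol m-2 s-1).  The light steady state is S* = F/k.
#'
#' @param s0 Initial DMADP pool (nmol m-2).
#' @param f_supply MEP supply flux under light (nmol m-2 s-1).
#' @param k_isps Apparent isoprene synthase rate constant (s-1), > 0.
#' @param e_dark_floor Residual dark emission floor (nmol m-2 s-1, >= 0).
#' @return A list of class `kinetic_params`.
#' @examples
#' kinetic_params(s0 = 300, f_supply = 15, k_isps = 0.05)
#' @export
kinetic_params <- function(s0, f_supply, k_isps, e_dark_floor = 0) {
  vals <- c(s0 = s0, f_supply = f_supply, k_isps = k_isps,
            e_dark_floor = e_dark_floor)
  if (any(!is.finite(vals))) {
    abort(paste0("non-finite kinetic parameter: ",
                 paste(names(vals)[!is.finite(vals)], collapse = ", ")))
  }
  if (any(vals < 0)) {
    abort(paste0("negative kinetic parameter: ",
                 paste(names(vals)[vals < 0], collapse = ", ")))
  }
  if (k_isps <= 0) abort("k_isps must be > 0")
  structure(as.list(vals), class = "kinetic_params")
}

#' Light/dark protocol
#'
#' Piecewise-constant illumination schedule: a light hold followed by darkness
#' (the post-illumination decay tail).  The dark transition is instantaneous
#' unless `supply_lag` is set, in which case the MEP supply decays
#' exponentially with that time constant after light-off instead of stopping
#' in one sample.
#'
#' @param light_s Duration of the light hold (s).
#' @param dark_s Duration of the dark tail (s).
#' @param ppfd_light PPFD during the light phase (umol m-2 s-1).
#' @param dt Sampling interval (s), default 1 (1 Hz acquisition).
#' @param supply_lag Optional exponential lag (s) of supply cessation at
#'   darkness; 0 means instantaneous cut.
#' @return A list of class `light_protocol` with a sample-time grid.
#' @export
light_protocol <- function(light_s = 300, dark_s = 300, ppfd_light = 1000,
                           dt = 1, supply_lag = 0) {
  stopifnot(dt > 0, light_s >= 0, dark_s > 0, ppfd_light >= 0, supply_lag >= 0)
  times <- seq(0, light_s + dark_s, by = dt)
  structure(
    list(light_s = light_s, dark_s = dark_s, ppfd_light = ppfd_light,
         dt = dt, supply_lag = supply_lag, times = times),
    class = "light_protocol"
  )
}

protocol_supply_factor <- function(protocol) {
  t <- protocol$times
  L <- as.numeric(t < protocol$light_s)
  if (protocol$supply_lag > 0) {
    dark <- t >= protocol$light_s
    L[dark] <- exp(-(t[dark] - protocol$light_s) / protocol$supply_lag)
  }
  L
}

#' Simulate DMADP pool and isoprene emission dynamics
#'
#' Integrates the single-pool model of [kinetic_params()] over a
#' [light_protocol()].  Within each constant-supply segment the exact
#' closed-form solution
#' \eqn{S(t) = S_{eq} + (S_0 - S_{eq}) e^{-k t}} with
#' \eqn{S_{eq} = F L / k} is used, stepped sample by sample, so the grid
#' solution carries no integration error for piecewise-constant supply.
#' With a nonzero `supply_lag` the dark segment is integrated with an exact
#' exponential-input update per step.
#'
#' @param params A [kinetic_params()] object.
#' @param protocol A [light_protocol()] object.
#' @return A tibble with columns `time_s`, `ppfd`, `supply` (nmol m-2 s-1),
#'   `pool` (S, nmol m-2) and `emission` (I, nmol m-2 s-1).
#' @examples
#' p <- kinetic_params(s0 = 300, f_supply = 15, k_isps = 0.05)
#' simulate_pool_dynamics(p, light_protocol(light_s = 60, dark_s = 120))
#' @export
simulate_pool_dynamics <- function(params, protocol) {
  stopifnot(inherits(params, "kinetic_params"), inherits(protocol, "light_protocol"))
  t <- protocol$times
  dt <- protocol$dt
  k <- params$k_isps
  L <- protocol_supply_factor(protocol)
  n <- length(t)
  S <- numeric(n)
  S[1] <- params$s0
  ek <- exp(-k * dt)
  for (i in seq_len(n - 1)) {
    F_i <- params$f_supply * L[i]
    if (protocol$supply_lag > 0 && t[i] >= protocol$light_s) {
      # exponential-input exact step: dS/dt = F0 e^(-(t-t0)/lag) - kS
      a <- 1 / protocol$supply_lag
      if (abs(k - a) < 1e-12) {
        S[i + 1] <- S[i] * ek + F_i * dt * ek
      } else {
        S[i + 1] <- S[i] * ek + F_i / (k - a) * (exp(-a * dt) - ek)
      }
    } else {
      S_eq <- F_i / k
      S[i + 1] <- S_eq + (S[i] - S_eq) * ek
    }
  }
  tibble::tibble(
    time_s = t,
    ppfd = ifelse(t < protocol$light_s, protocol$ppfd_light, 0),
    supply = params$f_supply * L,
    pool = S,
    emission = k * S + params$e_dark_floor
  )
}
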