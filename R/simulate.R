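#' Four-parameter logistic in temperature
#'
#' Shared sigmoid family used by the simulator's temperature responses and by
#' the response-model fits: \eqn{y(T) = y_{min} + (y_{max} - y_{min}) /
#' (1 + e^{-(T - T_{mid}) / s})}.  A negative `scale` gives a decreasing
#' response.
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param y_min,y_max Lower/upper asymptotes (response units).
#' @param t_mid Midpoint temperature (degrees C).
#' @param scale Steepness scale (degrees C); sign sets direction.
#' @return Numeric vector of responses.
#' @export
logistic4 <- function(t_leaf, y_min, y_max, t_mid, scale) {
  y_min + (y_max - y_min) / (1 + exp(-(t_leaf - t_mid) / scale))
}

#' Treatment factorial grid
#'
#' The default experimental design: four steady-state leaf temperatures
#' (25, 30, 35, 40 degrees C) crossed with two CO2 levels (400, 800
#' umol mol-1), six replicate leaves per cell, i.e. 48 leaves in total.
#'
#' @param temperatures Leaf temperature levels (degrees C).
#' @param co2_levels CO2 mole fractions (umol mol-1).
#' @param replicates Replicate leaves per treatment cell.
#' @param ppfd_light Saturating PPFD during the light phase (umol m-2 s-1).
#' @return A tibble with one row per leaf: `t_leaf_c`, `co2`, `replicate`,
#'   `ppfd_light`, `trace_id`.
#' @export
treatment_grid <- function(temperatures = c(25, 30, 35, 40),
                           co2_levels = c(400, 800),
                           replicates = 6,
                           ppfd_light = 1000) {
  tidyr::expand_grid(
    t_leaf_c = temperatures,
    co2 = co2_levels,
    replicate = seq_len(replicates)
  ) |>
    dplyr::mutate(
      ppfd_light = ppfd_light,
      trace_id = sprintf("T%02d_C%03d_r%d", .data$t_leaf_c, .data$co2, .data$replicate)
    )
}

#' Default temperature dependence of the apparent IspS rate constant
#'
#' Arrhenius-type (log-linear in 1/T) increase, parameterized by the value at
#' 25 degrees C and an activation temperature.  The defaults span roughly
#' 0.012 s-1 at 25 C to 0.07 s-1 at 40 C, the magnitude range reported for
#' poplar leaves between the thermal optimum and acute heat.
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param k_ref Rate constant at `t_ref` (s-1).
#' @param ea_over_r Activation energy over the gas constant (K).
#' @param t_ref Reference temperature (degrees C).
#' @return Rate constant (s-1).
#' @export
k_isps_default <- function(t_leaf, k_ref = 0.012, ea_over_r = 11000,
                           t_ref = 25) {
  k_ref * exp(ea_over_r * (1 / (t_ref + 273.15) - 1 / (t_leaf + 273.15)))
}

#' Default steady-state DMADP pool surface
#'
#' Sigmoidal expansion of the light steady-state DMADP pool with temperature,
#' larger and earlier under elevated CO2: the defaults place the pool near
#' 110-125 nmol m-2 at 25 C, near 200 (400 ppm) vs 320 (800 ppm) nmol m-2 at
#' 35 C, and near 360 (400 ppm) vs 460 (800 ppm) nmol m-2 at 40 C,
#' emulating the observed CO2-driven divergence of precursor pools under
#' acute heat.
#'
#' @param t_leaf Leaf temperature (degrees C).
#' @param co2 CO2 mole fraction (umol mol-1).
#' @return Steady-state pool S* (nmol m-2).
#' @export
dmadp_pool_default <- function(t_leaf, co2) {
  elevated <- co2 >= 600
  ifelse(elevated,
    logistic4(t_leaf, y_min = 120, y_max = 480, t_mid = 34.5, scale = 2.0),
    logistic4(t_leaf, y_min = 110, y_max = 420, t_mid = 37.0, scale = 2.2)
  )
}

#' Default net assimilation surface
#'
#' Net CO2 assimilation under saturating light, declining sigmoidally from
#' the thermal optimum (approx. 14 umol m-2 s-1 at 25 C under 400 ppm, ~30%
#' higher under 800 ppm) to near-collapse (< 2 umol m-2 s-1 at 40 C under
#' ambient CO2).  Emitted as treatment-level metadata, not mechanistically
#' modelled.
#'
#' @inheritParams dmadp_pool_default
#' @return A_net (umol CO2 m-2 s-1).
#' @export
a_net_default <- function(t_leaf, co2) {
  elevated <- co2 >= 600
  ifelse(elevated,
    logistic4(t_leaf, y_min = 18.2, y_max = 1.5, t_mid = 35.5, scale = 1.5),
    logistic4(t_leaf, y_min = 14.0, y_max = 1.2, t_mid = 35.5, scale = 1.5)
  )
}

#' Default stress-burst parameters for the non-isoprene VOC groups
#'
#' Each group's baseline emission is a single sigmoid in temperature with a
#' CO2 multiplier applied to the burst amplitude at elevated CO2; ethanol is
#' biphasic (sum of two sigmoids: a moderate mid-temperature component that
#' elevated CO2 suppresses, and an acute high-temperature fermentation burst
#' that elevated CO2 amplifies).  Default anchors: methanol baseline approx.
#' 11 and approx. 36 nmol m-2 s-1 at 40 C for both CO2 levels; LOX products
#' approx. 2.4 nmol m-2 s-1 at 40 C / 800 ppm; short-chain acids approx.
#' 15.4 and ethanol approx. 50 nmol m-2 s-1 at 40 C / 800 ppm; reactive
#' carbonyls approx. 450 nmol m-2 s-1 at 40 C / 800 ppm.
#'
#' @return A tibble with one row per sigmoid component: `group`, `baseline`,
#'   `amplitude`, `t_mid`, `slope`, `co2_mult` (amplitude multiplier at
#'   elevated CO2), `component`.
#' @export
default_burst_params <- function() {
  tibble::tribble(
    ~group,      ~baseline, ~amplitude, ~t_mid, ~slope, ~co2_mult, ~component,
    "lox",       0.15,      2.13,       38.5,   1.2,    1.35,      1L,
    "carbonyls", 0.50,      220,        38.5,   1.0,    2.51,      1L,
    "methanol",  11.0,      29.7,       37.5,   1.5,    1.00,      1L,
    "acids",     0.30,      11.6,       38.5,   1.2,    1.68,      1L,
    "ethanol",   0.20,      2.00,       29.5,   0.8,    0.30,      1L,
    "ethanol",   0.00,      15.1,       38.8,   0.9,    4.10,      2L
  )
}

#' Stress-VOC baseline emission at a treatment condition
#'
#' Evaluates the (sum-of-)sigmoid burst profile for one of the five
#' non-isoprene VOC groups at a leaf temperature and CO2 level.  Single-
#' sigmoid groups are monotone non-decreasing in temperature; ethanol's
#' two-component profile reproduces its biphasic response.
#'
#' @param group One of `"lox"`, `"carbonyls"`, `"methanol"`, `"acids"`,
#'   `"ethanol"`.
#' @param t_leaf Leaf temperature (degrees C).
#' @param co2 CO2 mole fraction (umol mol-1).
#' @param burst_params Parameter table as from [default_burst_params()].
#' @return Emission rate (nmol m-2 s-1), non-negative.
#' @examples
#' stress_burst_profile("methanol", c(25, 40), 400)
#' @export
stress_burst_profile <- function(group, t_leaf, co2,
                                 burst_params = default_burst_params()) {
  if (length(group) != 1 || !group %in% burst_params$group) {
    abort(sprintf("unknown VOC group '%s'; expected one of: %s",
                  paste(group, collapse = ","),
                  paste(unique(burst_params$group), collapse = ", ")))
  }
  pars <- burst_params[burst_params$group == group, , drop = FALSE]
  elevated <- co2 >= 600
  out <- 0
  for (i in seq_len(nrow(pars))) {
    amp <- pars$amplitude[i] * ifelse(elevated, pars$co2_mult[i], 1)
    out <- out + logistic4(t_leaf, pars$baseline[i],
                           pars$baseline[i] + amp,
                           pars$t_mid[i], pars$slope[i])
  }
  pmax(out, 0)
}

#' Simulator configuration
#'
#' Bundles everything [generate_experiment()] needs: the factorial design,
#' chamber geometry, acquisition protocol, noise model and the default
#' physiological response surfaces.  All pieces are replaceable.
#'
#' @param grid Treatment design, see [treatment_grid()].
#' @param geometry Chamber geometry, see [chamber_geometry()].
#' @param registry Channel registry, see [default_channel_registry()].
#' @param light_s Light-hold duration before darkening (s).
#' @param dark_s Dark-tail duration (s); `NULL` (default) uses
#'   `max(300, ceiling(6 / k))` per leaf so the decay is exhausted.
#' @param dt Sampling interval (s).
#' @param cv_mult Multiplicative noise coefficient of variation on mixing
#'   ratios (default 0.03, typical of 1 Hz PTR-TOF channel precision).
#' @param sd_add Additive noise floor on mixing ratios (nmol mol-1).
#' @param chi_bg Inlet/background mixing ratio applied to every channel
#'   (nmol mol-1); what empty-chamber blanks measure.
#' @param e_dark_floor Residual dark isoprene emission floor (nmol m-2 s-1).
#' @param supply_lag Exponential supply-cessation lag at darkness (s);
#'   0 = instantaneous cut.
#' @param k_fun,pool_fun,a_net_fun Response surfaces `f(t_leaf)` /
#'   `f(t_leaf, co2)` for the rate constant, steady-state pool and A_net.
#' @param burst_params Stress-burst table, see [default_burst_params()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid = treatment_grid(),
                       geometry = chamber_geometry(),
                       registry = default_channel_registry(),
                       light_s = 300, dark_s = NULL, dt = 1,
                       cv_mult = 0.03, sd_add = 0.02, chi_bg = 0.5,
                       e_dark_floor = 0.05, supply_lag = 0,
                       k_fun = k_isps_default,
                       pool_fun = dmadp_pool_default,
                       a_net_fun = a_net_default,
                       burst_params = default_burst_params()) {
  stopifnot(cv_mult >= 0, sd_add >= 0, chi_bg >= 0, light_s > 0, dt > 0)
  validate_registry(registry)
  structure(
    list(grid = grid, geometry = geometry, registry = registry,
         light_s = light_s, dark_s = dark_s, dt = dt,
         cv_mult = cv_mult, sd_add = sd_add, chi_bg = chi_bg,
         e_dark_floor = e_dark_floor, supply_lag = supply_lag,
         k_fun = k_fun, pool_fun = pool_fun, a_net_fun = a_net_fun,
         burst_params = burst_params),
    class = "sim_config"
  )
}

add_channel_noise <- function(chi, cv_mult, sd_add) {
  n <- length(chi)
  chi * (1 + stats::rnorm(n, 0, cv_mult)) + stats::rnorm(n, 0, sd_add)
}

#' Simulate one leaf trace
#'
#' Builds the full 1 Hz channel table for a single leaf at one treatment
#' cell: isoprene from the first-order pool model, the five stress groups as
#' temperature/CO2-dependent baselines (split equally across a group's
#' member channels), all passed through the chamber mass balance on top of
#' the inlet background, with multiplicative plus additive channel noise.
#'
#' @param cell One-row tibble with `t_leaf_c`, `co2`, `replicate`,
#'   `ppfd_light`, `trace_id` (a [treatment_grid()] row).
#' @param config A [sim_config()].
#' @return A list with `trace` (tibble: `time_s, ppfd, t_leaf_c,
#'   co2_umol_mol, q_flow_umol_s, a_net`, and one `chi_<compound>` column per
#'   registry channel) and `truth` (one-row tibble of ground-truth
#'   parameters).
#' @export
sim_trace <- function(cell, config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$k_fun(cell$t_leaf_c)
  s_star <- config$pool_fun(cell$t_leaf_c, cell$co2)
  a_net <- config$a_net_fun(cell$t_leaf_c, cell$co2)
  dark_s <- config$dark_s %||% max(300, ceiling(6 / k))
  protocol <- light_protocol(config$light_s, dark_s,
                             ppfd_light = cell$ppfd_light, dt = config$dt,
                             supply_lag = config$supply_lag)
  params <- kinetic_params(s0 = s_star, f_supply = k * s_star, k_isps = k,
                           e_dark_floor = config$e_dark_floor)
  dyn <- simulate_pool_dynamics(params, protocol)

  geom <- config$geometry
  reg <- config$registry
  chans <- split(reg$compound, reg$group)
  chi <- list()
  # isoprene channel from pool kinetics
  chi[["isoprene"]] <- simulate_chamber(dyn$emission, chamber_geometry(
    geom$q_flow, geom$a_leaf, geom$n_chamber, chi_in = config$chi_bg
  ), dt = config$dt)
  # stress groups: constant group emission split equally over member channels
  group_em <- numeric(0)
  for (g in setdiff(names(chans), "isoprene")) {
    em_g <- stress_burst_profile(g, cell$t_leaf_c, cell$co2, config$burst_params)
    group_em[g] <- em_g
    per_chan <- em_g / length(chans[[g]])
    for (cmp in chans[[g]]) {
      chi[[cmp]] <- simulate_chamber(rep(per_chan, nrow(dyn)), chamber_geometry(
        geom$q_flow, geom$a_leaf, geom$n_chamber, chi_in = config$chi_bg
      ), dt = config$dt)
    }
  }
  chi <- purrr::map(chi, add_channel_noise,
                    cv_mult = config$cv_mult, sd_add = config$sd_add)
  names(chi) <- paste0("chi_", names(chi))

  trace <- tibble::tibble(
    time_s = dyn$time_s,
    ppfd = dyn$ppfd,
    t_leaf_c = cell$t_leaf_c,
    co2_umol_mol = cell$co2,
    q_flow_umol_s = geom$q_flow,
    a_net = a_net + stats::rnorm(nrow(dyn), 0, 0.02 * abs(a_net))
  )
  trace <- dplyr::bind_cols(trace, tibble::as_tibble(chi))

  truth <- tibble::tibble(
    trace_id = cell$trace_id,
    t_leaf_c = cell$t_leaf_c, co2 = cell$co2, replicate = cell$replicate,
    s_pool_true = s_star, k_isps_true = k, f_supply_true = k * s_star,
    e_ss_true = k * s_star + config$e_dark_floor,
    e_dark_floor_true = config$e_dark_floor,
    a_net_true = a_net, dark_s = dark_s,
    dark_tail_short = dark_s < 5 / k
  )
  for (g in names(group_em)) truth[[paste0("flux_", g, "_true")]] <- group_em[[g]]
  if (truth$dark_tail_short) {
    warn(sprintf("trace %s: dark tail (%g s) shorter than 5/k (%.0f s); decay not exhausted",
                 cell$trace_id, dark_s, 5 / k))
  }
  list(trace = trace, truth = truth)
}

#' Simulate an empty-chamber blank trace
#'
#' Same schema as a leaf trace but with no leaf enclosed: every channel sits
#' at the inlet background plus noise.  Used to exercise and test blank
#' correction under matched environmental conditions.
#'
#' @param cell Treatment-cell row (as in [sim_trace()]); `replicate` is
#'   ignored, one blank per cell is conventional.
#' @param config A [sim_config()].
#' @param duration_s Blank duration (s).
#' @return A trace tibble (same columns as [sim_trace()]'s `trace`).
#' @export
sim_blank <- function(cell, config, duration_s = 120) {
  t <- seq(0, duration_s, by = config$dt)
  reg <- config$registry
  chi <- purrr::map(setNames(reg$compound, reg$compound), function(cmp) {
    add_channel_noise(rep(config$chi_bg, length(t)),
                      config$cv_mult, config$sd_add)
  })
  names(chi) <- paste0("chi_", names(chi))
  dplyr::bind_cols(
    tibble::tibble(
      time_s = t, ppfd = cell$ppfd_light, t_leaf_c = cell$t_leaf_c,
      co2_umol_mol = cell$co2, q_flow_umol_s = config$geometry$q_flow,
      a_net = 0
    ),
    tibble::as_tibble(chi)
  )
}

#' Generate a full simulated factorial experiment
#'
#' Runs [sim_trace()] over every leaf of the design and [sim_blank()] over
#' every treatment cell, under a single seed: identical seeds give
#' bit-identical output.  The default design is 4 temperatures x 2 CO2
#' levels x 6 replicates = 48 leaf traces.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed controlling every random draw.
#' @return A list with `traces` (tibble: design columns plus a `trace`
#'   list-column), `truth` (one row per leaf) and `blanks` (tibble keyed by
#'   treatment cell with a `blank` list-column).
#' @examples
#' \donttest{
#' exp <- generate_experiment(sim_config(), seed = 1)
#' nrow(exp$truth)  # 48
#' }
#' @export
generate_experiment <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(seed), {
    sims <- purrr::map(seq_len(nrow(config$grid)), function(i) {
      sim_trace(config$grid[i, ], config)
    })
    cells <- dplyr::distinct(config$grid, .data$t_leaf_c, .data$co2,
                             .keep_all = TRUE)
    blanks <- purrr::map(seq_len(nrow(cells)), function(i) {
      sim_blank(cells[i, ], config)
    })
    list(
      traces = dplyr::mutate(config$grid, trace = purrr::map(sims, "trace")),
      truth = purrr::list_rbind(purrr::map(sims, "truth")),
      blanks = dplyr::mutate(
        dplyr::select(cells, "t_leaf_c", "co2"),
        blank = blanks
      )
    )
  })
}
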