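# shared fixtures, all generated in code

# pure exponential decay flux series with a light hold, on a 1 Hz grid
make_decay_series <- function(k = 0.05, amp = 15, e_dark = 0, light_s = 100,
                              dark_s = 300, dt = 1, cv = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- seq(0, light_s + dark_s, by = dt)
  flux <- ifelse(t < light_s, amp + e_dark,
                 amp * exp(-k * (t - light_s)) + e_dark)
  if (cv > 0) flux <- flux * (1 + rnorm(length(flux), 0, cv))
  tibble::tibble(time_s = t, ppfd = ifelse(t < light_s, 1000, 0), flux = flux)
}

# one-cell, one-replicate simulator config for fast tests
tiny_config <- function(...) {
  sim_config(
    grid = treatment_grid(temperatures = 30, co2_levels = 400, replicates = 1),
    ...
  )
}

# reduced factorial (all 8 cells, 2 replicates) for mid-weight tests
small_config <- function(...) {
  sim_config(grid = treatment_grid(replicates = 2), ...)
}
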