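test_that("the dark transition is found at the PPFD step", {
  d <- make_decay_series(light_s = 100)
  expect_equal(detect_transition(d), 100)
  flat <- d
  flat$ppfd <- 1000
  expect_error(detect_transition(flat), "no dark transition")
})

test_that("change-point fallback finds the transition within 2 s under noise", {
  d <- make_decay_series(k = 0.05, light_s = 100, cv = 0.03, seed = 11)
  d$ppfd <- NULL
  expect_lte(abs(detect_transition(d) - 100), 2)
  # across seeds
  errs <- vapply(1:20, function(s) {
    dd <- make_decay_series(k = 0.05, light_s = 100, cv = 0.03, seed = s)
    dd$ppfd <- NULL
    abs(detect_transition(dd) - 100)
  }, numeric(1))
  expect_lte(median(errs), 2)
})

test_that("steady-state estimation averages the pre-dark window and flags drift", {
  d <- make_decay_series(k = 0.05, amp = 15, light_s = 100)
  ss <- estimate_steady_state(d, 100)
  expect_equal(ss$e_ss, 15)
  expect_false(ss$drift_flag)
  # noisy: within 3 SEM
  dn <- make_decay_series(k = 0.05, amp = 15, light_s = 100, cv = 0.03, seed = 4)
  ssn <- estimate_steady_state(dn, 100)
  expect_lt(abs(ssn$e_ss - 15), 3 * 0.03 * 15 / sqrt(60))
  # ramping flux raises the drift flag
  dr <- d
  lit <- dr$time_s < 100
  dr$flux[lit] <- 15 + 0.05 * dr$time_s[lit]
  expect_true(estimate_steady_state(dr, 100)$drift_flag)
})

test_that("dark baseline is taken from the exhausted terminal window", {
  d <- make_decay_series(k = 0.05, amp = 15, e_dark = 0.2, light_s = 100,
                         dark_s = 300)
  bl <- estimate_dark_baseline(d, 100)
  expect_equal(bl$e_dark, 0.2, tolerance = 1e-3)
  expect_false(bl$baseline_not_reached)
  # truncated decay: terminal window still sloping
  dt_trunc <- d[d$time_s <= 140, ]
  blt <- estimate_dark_baseline(dt_trunc, 100)
  expect_true(blt$baseline_not_reached)
  # exactly zero tail
  d0 <- make_decay_series(k = 0.5, amp = 15, e_dark = 0, light_s = 50,
                          dark_s = 200)
  expect_equal(estimate_dark_baseline(d0, 50)$e_dark, 0, tolerance = 1e-6)
})

test_that("pool integration matches the analytic integral", {
  d <- make_decay_series(k = 0.05, amp = 15, e_dark = 0.3, light_s = 100,
                         dark_s = 400)
  s <- integrate_pool(d, 100, e_dark = 0.3)
  expect_equal(s, 15 / 0.05, tolerance = 0.01)
  # flat series integrates to zero
  flat <- tibble::tibble(time_s = 0:100, flux = 0.3)
  expect_equal(integrate_pool(flat, 10, 0.3), 0)
  # overestimated baseline is rejected
  expect_error(integrate_pool(flat, 10, 5), "baseline overestimated")
  # 1 Hz trapezoid vs fine-grid oracle within 1%
  fine <- make_decay_series(k = 0.05, amp = 15, light_s = 10, dark_s = 400,
                            dt = 0.001)
  s_fine <- integrate_pool(fine, 10, 0)
  s_1hz <- integrate_pool(make_decay_series(k = 0.05, amp = 15, light_s = 10,
                                            dark_s = 400), 10, 0)
  expect_equal(s_1hz, s_fine, tolerance = 0.01)
})

test_that("rate-constant estimators are exact on noise-free exponentials", {
  d <- make_decay_series(k = 0.05, amp = 15, light_s = 100)
  kf <- fit_rate_constant(d, 100, e_ss = 15, e_dark = 0)
  expect_equal(kf$k_loglin, 0.05, tolerance = 1e-6)
  expect_equal(kf$k_slope, 0.05, tolerance = 1e-4)
  expect_equal(kf$r2_loglin, 1)
  # dimensional analysis: stretching the time axis by 2 halves the estimates
  d2 <- d
  d2$time_s <- d2$time_s * 2
  kf2 <- fit_rate_constant(d2, 200, e_ss = 15, e_dark = 0)
  expect_equal(kf2$k_loglin, kf$k_loglin / 2, tolerance = 1e-6)
  expect_equal(kf2$k_slope, kf$k_slope / 2, tolerance = 1e-4)
  # no signal above the baseline is rejected
  flat <- tibble::tibble(time_s = 0:200, flux = 1)
  expect_error(fit_rate_constant(flat, 100, 1, 1), "no decay signal")
})

test_that("noisy rate recovery stays within 10% in the median (k = 0.07, 10 s window)", {
  w <- decay_windows(initial_window = 10)
  errs <- vapply(1:200, function(s) {
    d <- make_decay_series(k = 0.07, amp = 20, light_s = 60, dark_s = 150,
                           cv = 0.03, seed = 1000 + s)
    kf <- fit_rate_constant(d, 60, e_ss = 20, e_dark = 0, windows = w)
    abs(kf$k_loglin - 0.07) / 0.07
  }, numeric(1))
  expect_lte(median(errs), 0.10)
})

test_that("the full decay analysis satisfies the first-order identity", {
  d <- make_decay_series(k = 0.05, amp = 15, e_dark = 0.2, light_s = 100,
                         dark_s = 300)
  fit <- analyze_decay(d)
  r <- glance(fit)
  # S * k = E_ss - E_dark for first-order decay
  expect_equal(r$s_pool * r$k_loglin, r$e_ss - r$e_dark, tolerance = 0.01)
  # the three estimators agree within 1% on noise-free data
  expect_equal(r$k_slope / r$k_loglin, 1, tolerance = 0.01)
  expect_equal(r$k_ratio / r$k_loglin, 1, tolerance = 0.01)
  expect_equal(tidy(fit)$term[4], "s_pool")
  # stage errors carry the stage name
  no_dark <- d[d$time_s < 100, ]
  expect_error(analyze_decay(no_dark), "detect_transition")
})

test_that("pool estimates increase strictly with the generating pool size", {
  pools <- c(50, 150, 300, 500)
  k <- 0.04
  est <- vapply(pools, function(S0) {
    d <- make_decay_series(k = k, amp = k * S0, light_s = 60, dark_s = 300)
    glance(analyze_decay(d))$s_pool
  }, numeric(1))
  expect_true(all(diff(est) > 0))
  expect_equal(est, pools, tolerance = 0.03)
})

test_that("recovery bias vanishes as noise -> 0 and the tail lengthens", {
  for (k in c(0.01, 0.05, 0.1)) {
    S0 <- 250
    d <- make_decay_series(k = k, amp = k * S0, light_s = 100,
                           dark_s = ceiling(10 / k))
    r <- glance(analyze_decay(d))
    expect_equal(r$s_pool, S0, tolerance = 0.02)
    expect_equal(r$k_loglin, k, tolerance = 0.01)
  }
})

test_that("chamber washout biases k low and the dynamic balance removes >=80% of it", {
  k_true <- 0.05
  geom <- chamber_geometry(n_chamber = 2500)  # tau = 5 s
  cfg <- sim_config(
    grid = treatment_grid(temperatures = 35, co2_levels = 400, replicates = 1),
    geometry = geom, cv_mult = 0, sd_add = 0,
    k_fun = function(t) k_true
  )
  exp1 <- generate_experiment(cfg, seed = 1)
  naive <- analyze_experiment(exp1$traces, geom = geom, blanks = exp1$blanks,
                              dynamic = FALSE)
  dyn <- analyze_experiment(exp1$traces, geom = geom, blanks = exp1$blanks,
                            dynamic = TRUE)
  expect_lt(naive$k_loglin, k_true)           # biased low
  bias_naive <- abs(naive$k_loglin - k_true)
  bias_dyn <- abs(dyn$k_loglin - k_true)
  expect_lte(bias_dyn, 0.2 * bias_naive)
})
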