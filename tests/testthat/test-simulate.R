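test_that("the default design yields 48 traces with the expected schema", {
  cfg <- sim_config()
  expect_equal(nrow(cfg$grid), 48)
  exp1 <- generate_experiment(tiny_config(), seed = 1)
  tr <- exp1$traces$trace[[1]]
  expect_true(all(c("time_s", "ppfd", "t_leaf_c", "co2_umol_mol",
                    "q_flow_umol_s", "a_net", "chi_isoprene") %in% names(tr)))
  expect_equal(sum(grepl("^chi_", names(tr))), 16)
  # light steady state, abrupt transition, dark tail present
  expect_true(any(tr$ppfd > 0) && any(tr$ppfd == 0))
  expect_equal(nrow(exp1$truth), 1)
  expect_equal(nrow(exp1$blanks), 1)
})

test_that("a 1x1 grid with one replicate yields one trace", {
  cfg <- sim_config(grid = treatment_grid(temperatures = 30,
                                          co2_levels = 400, replicates = 1))
  exp1 <- generate_experiment(cfg, seed = 5)
  expect_equal(nrow(exp1$traces), 1)
})

test_that("the simulator is bit-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_experiment(cfg, seed = 42)
  b <- generate_experiment(cfg, seed = 42)
  expect_identical(a$traces$trace[[1]], b$traces$trace[[1]])
  expect_identical(a$truth, b$truth)
  c <- generate_experiment(cfg, seed = 43)
  expect_false(identical(a$traces$trace[[1]]$chi_isoprene,
                         c$traces$trace[[1]]$chi_isoprene))
})

test_that("stress burst profiles honor their anchors and shape constraints", {
  # degenerate sigmoid: zero amplitude stays at baseline
  bp <- default_burst_params()
  bp$amplitude <- 0
  expect_equal(stress_burst_profile("methanol", c(25, 32, 40), 400, bp),
               rep(11, 3), tolerance = 1e-3)
  # slope -> 0+ approaches a step at the midpoint
  bp2 <- default_burst_params()
  bp2$slope <- 1e-6
  v <- stress_burst_profile("acids", c(37, 40), 400, bp2)
  expect_equal(v[1], bp2$baseline[bp2$group == "acids"], tolerance = 1e-6)
  expect_equal(v[2], bp2$baseline[bp2$group == "acids"] +
                 bp2$amplitude[bp2$group == "acids"], tolerance = 1e-6)
  # methanol defaults: ~11 baseline, ~36 at 40 C, converged across CO2
  m25 <- stress_burst_profile("methanol", 25, 400)
  m40a <- stress_burst_profile("methanol", 40, 400)
  m40e <- stress_burst_profile("methanol", 40, 800)
  expect_equal(m25, 11, tolerance = 0.05)
  expect_equal(m40a, 36, tolerance = 0.1)
  expect_equal(m40e, m40a)
  # single-sigmoid groups are monotone non-decreasing in T
  tt <- seq(25, 40, by = 0.5)
  for (g in c("lox", "carbonyls", "methanol", "acids")) {
    for (co2 in c(400, 800)) {
      expect_true(all(diff(stress_burst_profile(g, tt, co2)) >= -1e-9))
    }
  }
  # unknown group is rejected
  expect_error(stress_burst_profile("monoterpenes", 30, 400), "unknown VOC group")
})

test_that("ethanol is biphasic: elevated CO2 suppresses the mid bump, amplifies the burst", {
  e30a <- stress_burst_profile("ethanol", 31, 400)
  e30e <- stress_burst_profile("ethanol", 31, 800)
  expect_gt(e30a, e30e)
  e40a <- stress_burst_profile("ethanol", 40, 400)
  e40e <- stress_burst_profile("ethanol", 40, 800)
  expect_gt(e40e, e40a)
  expect_equal(e40e, 50, tolerance = 0.05 * 50)
})

test_that("a short dark tail is flagged in the truth and warned about", {
  cfg <- tiny_config(dark_s = 30)
  expect_warning(exp1 <- generate_experiment(cfg, seed = 1), "dark tail")
  expect_true(exp1$truth$dark_tail_short[1])
})

test_that("default response surfaces sit in the reported physiological ranges", {
  # rate constant spans ~0.01-0.08 s-1 over 25-40 C
  expect_equal(k_isps_default(25), 0.012, tolerance = 1e-6)
  expect_gt(k_isps_default(40), 0.06)
  expect_lt(k_isps_default(40), 0.08)
  # pool: CO2-driven divergence at 35 C, peak near 430-470 at 40 C / 800 ppm
  expect_gt(dmadp_pool_default(35, 800), dmadp_pool_default(35, 400))
  expect_gt(dmadp_pool_default(40, 800), 430)
  expect_lt(dmadp_pool_default(40, 800), 470)
  # A_net collapses below 2 umol m-2 s-1 at 40 C under ambient CO2
  expect_lt(a_net_default(40, 400), 2)
  expect_gt(a_net_default(25, 800) / a_net_default(25, 400), 1.25)
})
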