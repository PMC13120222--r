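test_that("mass-balance flux conversion matches hand arithmetic", {
  g <- chamber_geometry(q_flow = 500, a_leaf = 6e-4)
  expect_equal(flux_from_mixing_ratio(1, 0, g), 500e-6 / 6e-4, tolerance = 1e-12)
  expect_equal(flux_from_mixing_ratio(1, 0, g), 0.8333, tolerance = 1e-4)
  expect_equal(flux_from_mixing_ratio(0, 0, g), 0)
  # halving the leaf area doubles the flux at fixed delta-chi
  g_half <- chamber_geometry(q_flow = 500, a_leaf = 3e-4)
  expect_equal(flux_from_mixing_ratio(1, 0, g_half),
               2 * flux_from_mixing_ratio(1, 0, g))
})

test_that("flux computation is linear in the mixing ratio", {
  g <- chamber_geometry()
  set.seed(1)
  chi1 <- runif(50); chi2 <- runif(50)
  a <- 2.5; b <- -0.7
  expect_equal(
    flux_from_mixing_ratio(a * chi1 + b * chi2, 0, g),
    a * flux_from_mixing_ratio(chi1, 0, g) + b * flux_from_mixing_ratio(chi2, 0, g)
  )
})

test_that("chamber simulation and flux computation are exact inverses", {
  g <- chamber_geometry(n_chamber = 0, chi_in = 0)
  em <- c(rep(15, 30), 15 * exp(-0.05 * 0:100))
  chi <- simulate_chamber(em, g)
  back <- flux_from_mixing_ratio(chi, 0, g)
  expect_equal(back, em, tolerance = 1e-12)
})

test_that("dynamic storage term recovers emission through a laggy chamber", {
  g <- chamber_geometry(n_chamber = 2500)  # tau = 5 s
  t <- 0:200
  em <- ifelse(t < 50, 10, 10 * exp(-0.05 * (t - 50)))
  chi <- simulate_chamber(em, g, dt = 1)
  naive <- flux_from_mixing_ratio(chi, 0, g)
  dyn <- flux_from_mixing_ratio(chi, 0, g, time_s = t, dynamic = TRUE)
  # the storage term removes most of the washout distortion mid-decay
  mid <- t > 55 & t < 100
  expect_lt(mean(abs(dyn[mid] - em[mid])), 0.35 * mean(abs(naive[mid] - em[mid])))
  expect_error(flux_from_mixing_ratio(chi, 0, g, dynamic = TRUE), "time_s")
})

test_that("blank correction subtracts the blank mean and keeps negatives", {
  x <- c(5, 6, 7)
  expect_equal(as.numeric(blank_correct(x, rep(0, 10))), x)
  corr <- blank_correct(x, c(2, 2, 2, 2))
  expect_equal(as.numeric(corr), x - 2)
  expect_equal(attr(corr, "blank_level"), 2)
  neg <- blank_correct(c(1, 1), c(3, 3))
  expect_equal(as.numeric(neg), c(-2, -2))  # retained, not clipped
  expect_error(blank_correct(x, numeric(0)), "no blank")
  expect_error(blank_correct(x, c(1, 2), mode = "pointwise"), "equal length")
})

test_that("a constant blank mixing ratio lowers flux by exactly Q*b/A", {
  cfg <- tiny_config(cv_mult = 0, sd_add = 0, chi_bg = 0)
  exp1 <- generate_experiment(cfg, seed = 1)
  tr <- exp1$traces$trace[[1]]
  g <- cfg$geometry
  b <- 0.8
  blank <- tr[1:50, ]
  for (col in grep("^chi_", names(blank), value = TRUE)) blank[[col]] <- b
  raw <- compute_fluxes(tr, g)
  corr <- compute_fluxes(tr, g, blank = blank)
  expect_equal(raw$flux_nmol_m2_s - corr$flux_nmol_m2_s,
               rep(g$q_flow * 1e-6 * b / g$a_leaf, nrow(raw)),
               tolerance = 1e-10)
  expect_true(all(corr$blank_corrected))
  expect_true(any(corr$negative))  # background-only channels go negative
})

test_that("group aggregation is additive, order-invariant and conservative", {
  reg <- default_channel_registry()
  fx <- tibble::tibble(
    trace_id = "t", time_s = rep(0:4, 3),
    compound = rep(c("formic_acid", "acetic_acid", "methanol"), each = 5),
    group = NA_character_,
    flux_nmol_m2_s = rep(c(1.0, 2.0, 5.0), each = 5),
    blank_corrected = FALSE, negative = FALSE
  )
  agg <- aggregate_groups(fx, reg)
  acids <- agg$flux_nmol_m2_s[agg$group == "acids"]
  expect_equal(acids, rep(3.0, 5))
  # single-member group equals its member
  expect_equal(agg$flux_nmol_m2_s[agg$group == "methanol"], rep(5.0, 5))
  # permutation invariance
  agg2 <- aggregate_groups(fx[sample.int(nrow(fx)), ], reg)
  expect_equal(
    dplyr::arrange(agg2, group, time_s)$flux_nmol_m2_s,
    dplyr::arrange(agg, group, time_s)$flux_nmol_m2_s
  )
  # conservation: sum over groups equals sum over compounds
  expect_equal(sum(agg$flux_nmol_m2_s), sum(fx$flux_nmol_m2_s))
  # unknown compound is rejected
  fx$compound[1] <- "limonene"
  expect_error(aggregate_groups(fx, reg), "absent from registry")
})
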