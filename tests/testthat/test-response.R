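test_that("sigmoid parameters are recovered from noisy factorial data", {
  set.seed(2)
  d <- tibble::tibble(t_leaf_c = rep(c(25, 30, 35, 40), each = 6))
  d$value <- logistic4(d$t_leaf_c, 1, 13, 36, 1.5) * (1 + rnorm(24, 0, 0.02))
  g <- glance(fit_sigmoid(d))
  expect_true(g$converged)
  expect_equal(g$y_min, 1, tolerance = 0.10)
  expect_equal(g$y_max, 13, tolerance = 0.10)
  expect_equal(g$t_mid, 36, tolerance = 0.10)
  expect_equal(g$scale, 1.5, tolerance = 0.10)
})

test_that("a constant response yields a degenerate flagged sigmoid", {
  d <- tibble::tibble(t_leaf_c = rep(c(25, 30, 35, 40), each = 3), value = 7)
  f <- fit_sigmoid(d)
  expect_true(f$degenerate)
  g <- glance(f)
  expect_equal(g$y_min, g$y_max)
  expect_error(fit_sigmoid(d[d$t_leaf_c < 35, ]), "4 distinct temperatures")
})

test_that("sigmoid predictions are invariant to unit relabeling and row order", {
  set.seed(3)
  d <- tibble::tibble(t_leaf_c = rep(c(25, 30, 35, 40), each = 6))
  d$value <- logistic4(d$t_leaf_c, 2, 10, 34, 2) + rnorm(24, 0, 0.1)
  f_c <- fit_sigmoid(d)
  # Fahrenheit relabeling: affine change of the temperature axis
  d_f <- dplyr::mutate(d, t_leaf_c = t_leaf_c * 9 / 5 + 32)
  f_f <- fit_sigmoid(d_f)
  t_test <- c(26, 31, 39)
  expect_equal(predict(f_f, t_test * 9 / 5 + 32), predict(f_c, t_test),
               tolerance = 1e-4)
  # permutation invariance
  f_p <- fit_sigmoid(d[sample.int(nrow(d)), ])
  expect_equal(predict(f_p, t_test), predict(f_c, t_test), tolerance = 1e-6)
})

test_that("substrate-control regression on exact proportionality is perfect", {
  set.seed(4)
  k <- 0.03
  d <- tibble::tibble(
    t_leaf_c = rep(c(25, 30, 35), each = 8),
    s_pool = runif(24, 100, 400)
  )
  d$e_ss <- k * d$s_pool
  f <- fit_substrate_control(d, "s_pool", "e_ss", exclude_temps = 40)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  expect_equal(f$slope, k, tolerance = 1e-10)
  expect_equal(f$n_used, 24)
  expect_equal(nrow(f$excluded), 0)
})

test_that("the exclusion set changes the fit and excluded points are recorded", {
  set.seed(5)
  d <- tibble::tibble(
    t_leaf_c = rep(c(25, 30, 35, 40), each = 6),
    s_pool = c(runif(18, 100, 300), runif(6, 350, 450))
  )
  d$e_ss <- 0.03 * d$s_pool
  # decoupled 40 C regime: emission jumps above the substrate line
  hot <- d$t_leaf_c == 40
  d$e_ss[hot] <- 0.08 * d$s_pool[hot]
  f_all <- fit_substrate_control(d, "s_pool", "e_ss", exclude_temps = numeric(0))
  f_exc <- fit_substrate_control(d, "s_pool", "e_ss", exclude_temps = 40)
  expect_gt(f_all$slope, f_exc$slope)
  expect_equal(nrow(f_exc$excluded), 6)
  expect_equal(f_exc$r2, 1, tolerance = 1e-12)
  # single-x data after exclusion is rejected
  d1 <- tibble::tibble(t_leaf_c = c(25, 25, 25, 40), s_pool = c(2, 2, 2, 5),
                       e_ss = c(1, 1, 1, 9))
  expect_error(fit_substrate_control(d1, "s_pool", "e_ss"), "single value")
  expect_error(
    fit_substrate_control(d, "s_pool", "e_ss", exclude_temps = c(25, 30, 35, 40)),
    "fewer than 3"
  )
})

test_that("pooled-variance t-test matches the textbook oracle to 1e-10", {
  d <- tibble::tibble(t_leaf_c = 25, co2 = rep(c(400, 800), each = 3),
                      v = c(1, 2, 3, 4, 5, 6))
  ct <- compare_treatments(d, "v")
  # hand-computed pooled-variance oracle
  m1 <- 2; m2 <- 5; sp2 <- (2 * 1 + 2 * 1) / 4
  t_hand <- (m1 - m2) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(abs(t_hand), 4, lower.tail = FALSE)
  expect_equal(ct$t_stat, t_hand, tolerance = 1e-10)
  expect_equal(ct$p_value, p_hand, tolerance = 1e-10)
  expect_equal(ct$df, 4)
  # cross-check against the reference implementation
  tt <- t.test(c(1, 2, 3), c(4, 5, 6), var.equal = TRUE)
  expect_equal(ct$t_stat, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(ct$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("t-test contracts: identical cells, df, stars and small-n skipping", {
  d <- tibble::tibble(t_leaf_c = rep(c(25, 30), each = 12),
                      co2 = rep(rep(c(400, 800), each = 6), 2),
                      v = rep(1:6, 4))
  ct <- compare_treatments(d, "v")
  expect_equal(ct$t_stat, c(0, 0))
  expect_equal(ct$p_value, c(1, 1))
  expect_equal(ct$df, c(10, 10))       # n1 = n2 = 6
  expect_equal(ct$stars, c("ns", "ns"))
  # a temperature with n < 2 in one cell is skipped, not dropped
  d2 <- dplyr::bind_rows(d, tibble::tibble(t_leaf_c = 35, co2 = 400, v = 1))
  ct2 <- compare_treatments(d2, "v")
  expect_equal(nrow(ct2), 3)
  expect_true(ct2$skipped[ct2$t_leaf_c == 35])
  expect_true(is.na(ct2$p_value[ct2$t_leaf_c == 35]))
  expect_equal(attr(ct2, "n_tests"), 2)
})

test_that("significance stars follow the 0.05/0.01/0.001 convention", {
  expect_equal(vocflux:::p_stars(c(0.04, 0.009, 0.0009, 0.5, NA)),
               c("*", "**", "***", "ns", NA))
})

test_that("the report assembles one tidy table per figure analog", {
  cfg <- small_config()
  exp1 <- generate_experiment(cfg, seed = 9)
  dec <- analyze_experiment(exp1$traces, blanks = exp1$blanks)
  gm <- experiment_group_means(exp1$traces, blanks = exp1$blanks)
  rep1 <- build_report(dec, group_means = gm)
  expect_equal(nrow(rep1$assimilation), 8)   # 4 T x 2 CO2 cells
  expect_equal(nrow(rep1$dmadp_pool), 8)
  expect_equal(nrow(rep1$substrate_control), 2)
  expect_equal(nrow(rep1$group_response), 6 * 8)
  expect_true(all(c("quantity", "t_stat", "p_value", "stars") %in%
                    names(rep1$ttests)))
  # regeneration from the same inputs is identical
  rep2 <- build_report(dec, group_means = gm)
  expect_identical(rep1$substrate_control, rep2$substrate_control)
  expect_identical(rep1$ttests, rep2$ttests)
})
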