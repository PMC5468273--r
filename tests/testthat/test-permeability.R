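test_that("relative volume applies the 3/2 area-to-volume power law", {
  expect_equal(relative_volume(c(2, 2)), c(1, 1))
  expect_equal(relative_volume(c(1, 1.21)), c(1, 1.331))
  expect_equal(relative_volume(c(1, 4)), c(1, 8))
  # scale invariance: rescaling all areas leaves V/V0 untouched
  a <- c(3, 3.1, 3.4, 3.9)
  expect_equal(relative_volume(a), relative_volume(2 * a))
  expect_error(relative_volume(c(1, -2, 3)), "index 2")
  expect_error(relative_volume(c(1, 2, 0)), "index 3")
})

test_that("initial slope is an OLS fit with free intercept and diagnostics", {
  t <- 0:30
  flat <- initial_slope(t, rep(2, 31), window = 20)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 1)

  line <- initial_slope(t, 1 + 1e-3 * t, window = 20)
  expect_equal(line$slope, 1e-3)
  expect_equal(line$r_squared, 1)
  expect_equal(line$n, 21L)

  expect_error(initial_slope(t, 1 + 1e-3 * t, window = 0.5), "at least 2")
  expect_error(initial_slope(0:5, 1:3, window = 5), "equal length")
})

test_that("slope of a noise-free simulation sits near the analytic slope", {
  co <- noise_free_cohort(pf = 2e-2, duration = 60, dt = 1)
  vv0 <- relative_volume(co$area)
  fit <- initial_slope(co$time, vv0, window = 10)
  # ~2% low: internal dilution shrinks the gradient across the 10-s window
  expect_equal(fit$slope, SLOPE_REF, tolerance = 0.03)
  expect_lt(fit$slope, SLOPE_REF)
  expect_gt(fit$r_squared, 0.999)
})

test_that("Pf formula anchor and exact slope-algebra round trip", {
  est <- estimate_pf(1e-3, oocyte_geometry(), osm_in = 200, osm_out = 70)
  expect_equal(est$coefficient, 8.55e-3, tolerance = 5e-4)
  expect_equal(est$coefficient, 1e-3 * 9e-4 / (0.045 * 18 * 1.3e-4))
  expect_equal(estimate_pf(0)$coefficient, 0)

  # estimate_pf inverts the analytic slope exactly, any pf
  for (pf in c(1e-4, 2e-3, 2e-2, 0.15)) {
    sl <- analytic_initial_slope(pf, oocyte_geometry(), 200, 70)
    expect_equal(estimate_pf(sl, osm_in = 200, osm_out = 70)$coefficient, pf)
  }
  # gradient magnitude: swapped osmolarities give the same positive Pf
  expect_equal(estimate_pf(1e-3, osm_in = 70, osm_out = 200)$coefficient,
               estimate_pf(1e-3, osm_in = 200, osm_out = 70)$coefficient)
  expect_error(estimate_pf(1e-3, osm_in = 70, osm_out = 70), "gradient")
})

test_that("Ps formula anchor and zero-gradient rejection", {
  est <- estimate_ps(5e-4, sol_in = 0, sol_out = 100)
  expect_equal(est$coefficient, 5e-4 * 9e-4 / (0.045 * 18 * 1e-4))
  expect_equal(signif(est$coefficient, 3), 5.56e-3)
  expect_equal(estimate_ps(0, sol_out = 100)$coefficient, 0)
  expect_error(estimate_ps(1e-3, sol_in = 100, sol_out = 100), "gradient")
})

test_that("water round trip: simulate then estimate recovers pf", {
  for (pf in c(5e-3, 2e-2)) {
    tr <- simulate_water_swelling(pf = pf, duration = 4, dt = 0.5)
    fit <- initial_slope(tr$time, tr$rel_volume, window = 2)
    est <- estimate_pf(fit, osm_in = 200, osm_out = 70)
    expect_equal(est$coefficient, pf, tolerance = 0.01)
  }
})

test_that("solute round trip recovers ps at the calibrated short window", {
  # the operational Ps formula is calibrated at T* = 2 V0/(Pf S) (2 s at
  # reference conditions); solute-entry saturation leaves a ~-15% bias there
  iso <- bath_condition(100, 100, "glycerol")
  tr <- simulate_solute_swelling(pf = 2e-2, ps = 5e-3, bath = iso,
                                 duration = 5, dt = 0.1)
  fit <- initial_slope(tr$time, tr$rel_volume, window = 2)
  est <- estimate_ps(fit, sol_in = 0, sol_out = 100)
  expect_equal(est$coefficient, 5e-3, tolerance = 0.15)
})

test_that("inhibition percent keeps its sign convention", {
  expect_equal(inhibition_percent(1, 1), 0)
  expect_equal(inhibition_percent(0.2, 1), 80)
  expect_equal(inhibition_percent(1.5, 1), -50)     # stimulation, unclipped
  expect_equal(inhibition_percent(1.5, 1, clip_negative = TRUE), 0)
  expect_error(inhibition_percent(1, 0), "coef_untreated")
})

test_that("two-group and multi-group comparisons use the right branch", {
  same <- list(a = c(1, 2, 3), b = c(1, 2, 3))
  ts <- compare_groups(same)
  expect_equal(ts$method, "welch_t")
  expect_equal(ts$statistic, 0)
  expect_equal(ts$p_value, 1)
  expect_equal(ts$estimate, 0)
  expect_null(ts$pairwise)

  three <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  an <- compare_groups(three)
  expect_equal(an$method, "anova_tukey")
  expect_equal(an$statistic, 0)
  expect_equal(nrow(an$pairwise), 3L)
  expect_true(all(an$pairwise$p_adj >= 0 & an$pairwise$p_adj <= 1))

  expect_error(compare_groups(list(a = 1, b = c(1, 2))), "singleton")
  expect_error(compare_groups(list(c(1, 2), c(3, 4))), "named")
})

test_that("well-separated groups are detected with near-certain power", {
  hits <- vapply(1:50, function(k) {
    vals <- aquaflux:::with_seed(500 + k, list(
      a = rnorm(5, 1, 0.1), b = rnorm(5, 2, 0.1)))
    compare_groups(vals)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
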