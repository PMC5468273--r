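test_that("closed membrane and zero gradient give flat trajectories", {
  flat1 <- simulate_water_swelling(pf = 0, osm_in0 = 200,
                                   bath = bath_condition(70))
  expect_equal(flat1$rel_volume, rep(1, nrow(flat1)))

  flat2 <- simulate_water_swelling(pf = 2e-2, osm_in0 = 70,
                                   bath = bath_condition(70))
  expect_equal(flat2$rel_volume, rep(1, nrow(flat2)), tolerance = 1e-9)
})

test_that("numeric initial slope matches the analytic Pf relation", {
  expect_equal(analytic_initial_slope(2e-2, oocyte_geometry(), 200, 70),
               SLOPE_REF, tolerance = 1e-12)
  tr <- simulate_water_swelling(pf = 2e-2, duration = 1, dt = 0.1)
  num <- (tr$rel_volume[2L] - tr$rel_volume[1L]) / 0.1
  expect_equal(num, SLOPE_REF, tolerance = 0.01)
})

test_that("trajectory is monotone, conserves osmolytes and hits equilibrium", {
  tr <- simulate_water_swelling(pf = 2e-2, duration = 2e4, dt = 20)
  expect_true(all(diff(tr$rel_volume) >= 0))
  # conserved amount: osm_in * V constant to integrator tolerance
  amount <- tr$osm_in * tr$rel_volume
  expect_lt(diff(range(amount)) / amount[1L], 1e-6)
  eq <- equilibrium_relative_volume(200, 70)
  expect_equal(eq, 200 / 70)
  expect_lt(max(tr$rel_volume), eq * (1 + 1e-6))  # no overshoot
  expect_equal(tr$rel_volume[nrow(tr)], eq, tolerance = 1e-3)
})

test_that("equilibrium ratio validates degenerate inputs", {
  expect_equal(equilibrium_relative_volume(70, 70), 1)
  expect_error(equilibrium_relative_volume(200, 0), "osm_out")
  expect_warning(out <- equilibrium_relative_volume(0, 70), "collapse")
  expect_equal(out, 0)
})

test_that("solute model: no Ps or no Pf means no swelling", {
  iso <- bath_condition(100, 100, "glycerol")
  no_ps <- simulate_solute_swelling(pf = 2e-2, ps = 0, bath = iso,
                                    duration = 30, dt = 1)
  expect_equal(no_ps$rel_volume, rep(1, nrow(no_ps)), tolerance = 1e-8)

  no_pf <- simulate_solute_swelling(pf = 0, ps = 5e-3, bath = iso,
                                    duration = 30, dt = 1)
  expect_equal(no_pf$rel_volume, rep(1, nrow(no_pf)), tolerance = 1e-8)
  # solute still enters even though water cannot follow
  expect_gt(no_pf$sol_in[nrow(no_pf)], 50)
})

test_that("coarse solute trajectory agrees with a fine-grid integration", {
  iso <- bath_condition(100, 100, "glycerol")
  coarse <- simulate_solute_swelling(pf = 2e-2, ps = 5e-3, bath = iso,
                                     duration = 5, dt = 0.1)
  fine <- simulate_solute_swelling(pf = 2e-2, ps = 5e-3, bath = iso,
                                   duration = 5, dt = 0.002)
  at <- match(round(coarse$time, 6), round(fine$time, 6))
  expect_false(anyNA(at))
  expect_equal(coarse$rel_volume, fine$rel_volume[at], tolerance = 1e-7)
  # solute bookkeeping: internal osm = impermeant osmolytes/V + sol_in
  imper <- (coarse$osm_in - coarse$sol_in) * coarse$rel_volume
  expect_lt(diff(range(imper)) / imper[1L], 1e-6)
})

test_that("small-time solute slope follows the quadratic expansion", {
  # early on, d(V/V0)/dt ~ (Pf S Vw/V0) * sol_in(t), sol_in ~ sol_out*b*t,
  # so the OLS slope over [0, T] is ~ (Pf S T / 2 V0) * Ps S Vw sol_out/V0.
  iso <- bath_condition(100, 100, "glycerol")
  tr <- simulate_solute_swelling(pf = 2e-2, ps = 5e-4, bath = iso,
                                 duration = 1, dt = 0.02)
  fit <- initial_slope(tr$time, tr$rel_volume, window = 0.5)
  geom <- oocyte_geometry()
  pred <- (2e-2 * geom$s * 0.25 / geom$v0) *
    (5e-4 * geom$s * geom$vw * 1e-4 / geom$v0)
  expect_equal(fit$slope, pred, tolerance = 0.05)
})

test_that("invalid model inputs are rejected", {
  expect_error(simulate_water_swelling(pf = -1), "pf")
  expect_error(simulate_water_swelling(pf = 1e-2, duration = 0), "duration")
  expect_error(simulate_water_swelling(pf = 1e-2,
                                       bath = bath_condition(100, 100,
                                                             "urea")),
               "sol_out")
  expect_error(simulate_solute_swelling(pf = 1e-2, ps = 1e-3,
                                        bath = bath_condition(70)),
               "sol_out")
  expect_error(bath_condition(-1), "osm_out")
  expect_error(bath_condition(70, 10, "water-only"), "water-only")
  expect_error(oocyte_geometry(v0 = 0), "v0")
})

test_that("mercury treatment scales Pf multiplicatively and reverses", {
  hg <- bath_condition(70, hg_treated = TRUE)
  rev <- bath_condition(70, hg_treated = TRUE, reversal = TRUE)
  expect_equal(effective_pf(2e-2, hg, hg_factor = 0.2), 4e-3)
  expect_equal(effective_pf(2e-2, rev, reversal_factor = 0.9), 1.8e-2)
  expect_equal(effective_pf(2e-2, bath_condition(70)), 2e-2)
  expect_equal(inhibition_percent(4e-3, 2e-2), 80)
})
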