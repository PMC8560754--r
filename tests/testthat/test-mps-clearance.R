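test_that("steady-state efflux and apparent clearance follow hand arithmetic", {
  tub <- effluent_series("d1", "drug", "control", "tubular",
                         time_h = seq(2, 24, 2),
                         conc_nM = c(20, 45, rep(50, 10)), flow_out = 60)
  ss <- steady_state_efflux(tub, window_start = 6)
  expect_equal(ss$efflux_rate, 50 * 60)  # nM * uL/h
  expect_equal(ss$vascular_conc, 1000)   # nominal fallback
  expect_equal(apparent_clearance(ss$efflux_rate, 1000), 3.0)
  # complete equilibration bound: efflux = Q * C -> CL_app = Q
  expect_equal(apparent_clearance(60 * 1000, 1000), 60)
  expect_equal(apparent_clearance(0, 1000), 0)
  expect_error(apparent_clearance(100, 0), "positive")
})

test_that("steady-state window rejects insufficient or censored samples", {
  short <- effluent_series("d", "x", "control", "tubular",
                           time_h = c(2, 4), conc_nM = c(10, 20))
  expect_error(steady_state_efflux(short, window_start = 6), "window_start")
  cens <- effluent_series("d", "x", "control", "tubular",
                          time_h = seq(2, 12, 2), conc_nM = rep(1, 6),
                          censored = rep(TRUE, 6))
  expect_error(steady_state_efflux(cens, window_start = 6), "non-censored")
  allzero <- effluent_series("d", "x", "control", "tubular",
                             time_h = seq(2, 12, 2), conc_nM = rep(0, 6))
  expect_equal(steady_state_efflux(allzero, window_start = 6)$efflux_rate, 0)
})

test_that("active clearance subtraction clamps negative differences", {
  expect_equal(active_from_apparent(3, 1), 2)
  expect_equal(active_from_apparent(1, 1), 0)
  expect_warning(out <- active_from_apparent(0.8, 1), "clamped")
  expect_equal(out, 0)
})

test_that("intrinsicization matches the flow-correction formula and inverts", {
  expect_equal(intrinsicize(3, 60), 60 * 3 / 57)
  expect_equal(intrinsicize(3, 60), 3.158, tolerance = 1e-3)
  expect_equal(intrinsicize(30, 60), 60)
  expect_equal(intrinsicize(0, 60), 0)
  expect_error(intrinsicize(60, 60), "flow-limited")
  # inverse property: apparentize(intrinsicize(x)) is the identity
  for (x in c(0, 0.5, 3, 30, 59.9)) {
    expect_equal(apparentize(intrinsicize(x, 60), 60), x, tolerance = 1e-12)
    expect_gte(intrinsicize(x, 60), x)
  }
  # CL_int grows without bound as CL_app approaches the flow
  expect_gt(intrinsicize(59.9999, 60), 1e6)
  # monotone in cl_app
  grid <- seq(0, 59, by = 0.5)
  expect_true(all(diff(vapply(grid, intrinsicize, numeric(1),
                              flow_endothelial = 60)) > 0))
})

test_that("permeability conversion is unit-consistent and proportional", {
  expect_equal(device_geometry()$surface_area, 0.0493, tolerance = 2e-3)
  geom <- device_geometry(surface_area = 0.0493)
  expect_equal(papp_from_intrinsic(4.93, geom), 27.8, tolerance = 1e-3)
  expect_equal(papp_from_intrinsic(0, geom), 0)
  half <- device_geometry(surface_area = 2 * geom$surface_area)
  expect_equal(papp_from_intrinsic(4.93, half),
               papp_from_intrinsic(4.93, geom) / 2)
})

test_that("noise-free synthetic donors round-trip through the full reduction", {
  truth <- noise_free_truth(cl_transport = 3, cl_passive = 1)
  arms <- generate_effluent_series(truth)
  # window far into the plateau so the exponential approach has decayed
  cs <- reduce_donor(arms$control, arms$inhibitor, window_start = 16,
                     nominal_conc = truth$vascular_conc_in)
  expect_equal(cs$cl_app_transport, 3, tolerance = 1e-3)
  expect_equal(cs$cl_int_transport, intrinsicize(3, 60), tolerance = 1e-3)
  expect_equal(cs$cl_int_passive, intrinsicize(1, 60), tolerance = 1e-3)
  truth_active <- intrinsicize(3, 60) - intrinsicize(1, 60)
  expect_equal(cs$cl_int_active, truth_active, tolerance = 1e-3)
  # referencing to the depleted vascular effluent instead overstates the
  # clearance by roughly the extraction ratio
  cs_eff <- reduce_donor(arms$control, arms$inhibitor, window_start = 16,
                         nominal_conc = truth$vascular_conc_in,
                         vascular_reference = "effluent")
  expect_gt(cs_eff$cl_app_transport, cs$cl_app_transport)
  # fully effective inhibitor with no active component
  t0 <- noise_free_truth(cl_transport = 1, cl_passive = 1)
  a0 <- generate_effluent_series(t0)
  cs0 <- reduce_donor(a0$control, a0$inhibitor, window_start = 16,
                      nominal_conc = 1000)
  expect_equal(cs0$cl_int_active, 0, tolerance = 1e-9)
})

test_that("a device parameterized like a strong-secretion donor round-trips", {
  # apparent values chosen so the intrinsic ones land near 14-15 uL/h of
  # active secretion and a permeability around 28e-6 cm/s
  geom <- device_geometry()
  cl_int_passive <- 4.93
  cl_int_active <- 14.1
  cl_app_passive <- apparentize(cl_int_passive, 60)
  cl_app_transport <- apparentize(cl_int_passive + cl_int_active, 60)
  truth <- mps_ground_truth(cl_app_transport, cl_app_passive, noise_cv = 0)
  arms <- generate_effluent_series(truth)
  cs <- reduce_donor(arms$control, arms$inhibitor, geom, window_start = 16,
                     nominal_conc = 1000)
  expect_equal(cs$cl_int_active, cl_int_active, tolerance = 1e-3)
  expect_equal(cs$papp, 27.8, tolerance = 0.01)
})

test_that("percent inhibition on synthetic donors recovers the generating fraction", {
  truth <- noise_free_truth(cl_transport = 4, cl_passive = 1)
  arms <- generate_effluent_series(truth)
  cs <- reduce_donor(arms$control, arms$inhibitor, window_start = 16,
                     nominal_conc = 1000)
  gen_frac <- 1 - intrinsicize(1, 60) / intrinsicize(4, 60)
  expect_equal(cs$cl_int_active / cs$cl_int_transport, gen_frac,
               tolerance = 1e-3)
})

test_that("inhibitor effect test equals the textbook pooled-variance t", {
  a <- c(10, 11, 9); b <- c(5, 6, 4)
  out <- inhibitor_effect_test(a, b)
  # hand-computed pooled t: sp2 = (2*1 + 2*1)/4 = 1, se = sqrt(2/3)
  t_hand <- (mean(a) - mean(b)) / sqrt(1 * (1 / 3 + 1 / 3))
  expect_equal(out$statistic, t_hand, tolerance = 1e-12)
  expect_equal(out$df, 4)
  expect_true(out$significant)
  same <- inhibitor_effect_test(c(1, 2, 3), c(2, 1, 3))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  const <- inhibitor_effect_test(c(2, 2), c(2, 2))
  expect_equal(const$statistic, 0)
  expect_equal(const$p_value, 1)
  expect_error(inhibitor_effect_test(1, c(1, 2)), ">= 2")
})
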