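test_that("distribution volume reconstruction matches the partition arithmetic", {
  phys <- body_physiology()
  # all-zero partitioning (tiny Kp) with no erythrocyte entry collapses to
  # plasma volume
  inert <- drug_model(renal_drug_params("x", 1, 0.55, 7, 1,
                                        split_subsegments(0, 3)),
                      kp = setNames(rep(1e-12, 12), phys$tissues$tissue))
  expect_equal(compute_vss(inert, phys), phys$v_plasma, tolerance = 1e-6)
  expect_error(compute_vss(drug_model(morphine_renal_params(),
                                      c(adipose = 1)), phys), "missing Kp")
})

test_that("hepatic clearance back-calculation inverts the well-stirred model", {
  expect_equal(hepatic_clearance_from_total(83.5, 8.24), 75.26)
  expect_equal(round(hepatic_clearance_from_total(83.5, 8.24), 1), 75.3)
  expect_equal(hepatic_clearance_from_total(10, 10), 0)
  expect_equal(hepatic_clearance_from_total(83.5, 0), 83.5)
  expect_error(hepatic_clearance_from_total(5, 6), "exceeds")
  expect_equal(backcalc_intrinsic_hepatic(75.3, 0.64, 1.08, 99.7), 520,
               tolerance = 2e-3)
  expect_equal(backcalc_intrinsic_hepatic(0, 0.64, 1.08, 99.7), 0)
  expect_error(backcalc_intrinsic_hepatic(100, 0.64, 1.08, 99.7), "extraction")
  for (frac in c(0.1, 0.5, 0.9)) {
    cl_h <- frac * 99.7
    expect_equal(well_stirred_hepatic(
      backcalc_intrinsic_hepatic(cl_h, 0.64, 1.08, 99.7), 0.64, 1.08, 99.7),
      cl_h, tolerance = 1e-10)
  }
})

test_that("parent elimination clearance emerges as hepatic plus renal", {
  parent <- morphine_model(clr = 8.24)
  dose <- dose_regimen(10, duration_h = 1 / 12)
  sim <- simulate_parent_metabolite(parent, m6g_model(), dose = dose,
                                    horizon = 24)
  res <- nca(sim$parent, dose, parent$renal$mol_weight)
  expect_equal(res$cl_L_h, parent$cl_h + 8.24, tolerance = 0.02)
  # mass conservation at every output time
  expect_lt(max(abs(sim$balance$parent_rel_error)), 0.005)
  expect_lt(max(abs(sim$balance$metabolite_rel_error)), 0.005)
})

test_that("the model is linear in dose and in the formation fraction", {
  d1 <- dose_regimen(5, duration_h = 1 / 12)
  d2 <- dose_regimen(10, duration_h = 1 / 12)
  p <- morphine_model(clr = 8.24)
  s1 <- simulate_parent_metabolite(p, m6g_model(), dose = d1, horizon = 12)
  s2 <- simulate_parent_metabolite(p, m6g_model(), dose = d2, horizon = 12)
  keep <- s1$parent$series$conc_nM > 1e-9
  expect_equal(s2$parent$series$conc_nM[keep] / s1$parent$series$conc_nM[keep],
               rep(2, sum(keep)), tolerance = 1e-6)
  # metabolite exposure scales with fm
  p_half <- morphine_model(clr = 8.24, fm_m6g = 0.05)
  s3 <- simulate_parent_metabolite(p_half, m6g_model(), dose = d1, horizon = 12)
  keepm <- s1$metabolite$series$conc_nM > 1e-9
  expect_equal(s3$metabolite$series$conc_nM[keepm] /
                 s1$metabolite$series$conc_nM[keepm],
               rep(0.5, sum(keepm)), tolerance = 1e-6)
  # no formation, no metabolite
  p0 <- morphine_model(clr = 8.24, fm_m6g = 0)
  s0 <- simulate_parent_metabolite(p0, m6g_model(), dose = d1, horizon = 6)
  expect_equal(max(s0$metabolite$series$conc_nM), 0)
})

test_that("moment-analysis Vss of a directly dosed metabolite matches the partition sum", {
  met <- m6g_model()
  phys <- body_physiology(sampling_site = "central_venous")
  dose <- dose_regimen(5, duration_h = 1 / 12)
  sim <- simulate_parent_metabolite(met, NULL, dose = dose, phys = phys,
                                    horizon = 48)
  res <- nca(sim$parent, dose, met$renal$mol_weight)
  expect_equal(res$vss_L, compute_vss(met, phys), tolerance = 0.05)
})

test_that("terminal slope is stable to halving solver tolerances", {
  p <- morphine_model(clr = 8.24)
  dose <- dose_regimen(10, duration_h = 1 / 12)
  lam <- function(rtol, atol) {
    sim <- simulate_parent_metabolite(p, NULL, dose = dose, horizon = 24,
                                      rtol = rtol, atol = atol)
    nca(sim$parent, dose, p$renal$mol_weight)$lambda_z
  }
  expect_equal(lam(1e-8, 1e-10), lam(5e-9, 5e-11), tolerance = 1e-6)
})
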