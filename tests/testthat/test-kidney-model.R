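test_that("fraction unionized follows Henderson-Hasselbalch", {
  expect_equal(fraction_unionized(7.4, 7.9), 0.240, tolerance = 2e-3)
  expect_equal(fraction_unionized(7.9, 7.9), 0.5)
  expect_equal(fraction_unionized(6.3, 9.12), 1.51e-3, tolerance = 1e-3)
  ph <- seq(4.5, 8, by = 0.1)
  f <- fraction_unionized(ph, 7.9)
  expect_true(all(f > 0 & f < 1))
  expect_true(all(diff(f) > 0))  # a base unionizes as pH rises
})

test_that("filtration-only kidney matches the fu*GFR closed form", {
  drug <- renal_drug_params("inert", fu_p = 0.64, blood_plasma_ratio = 1,
                            pka_base = 7.9, papp = 0,
                            secretion = split_subsegments(0, 3))
  clr <- simulate_renal_clearance(drug, kidney_physiology(gfr = 120))
  expect_equal(clr, 0.64 * 7.2, tolerance = 1e-8)
})

test_that("zero-permeability kidney adds the full secreted flux to filtration", {
  drug <- renal_drug_params("secreted", fu_p = 0.5, blood_plasma_ratio = 1,
                            pka_base = 8, papp = 0,
                            secretion = split_subsegments(12, 3))
  clr <- simulate_renal_clearance(drug, kidney_physiology())
  # no reabsorption pathway: CL_r = fu*GFR + CL_sec (secretion referenced
  # to total plasma concentration)
  expect_equal(clr, 0.5 * 7.2 + 12, tolerance = 1e-8)
})

test_that("ODE steady state matches the independent algebraic chain solution", {
  phys <- kidney_physiology()
  for (drug in list(morphine_renal_params(), m6g_renal_params())) {
    expect_equal(simulate_renal_clearance(drug, phys),
                 nephron_oracle_clr(drug, phys), tolerance = 1e-7)
  }
  # one-segment kidney: closed-form single-compartment balance
  phys1 <- kidney_physiology(
    area_weights = c(S1 = 1), segment_ph = 6.9,
    flow_out_mL_min = 60, volume_L = 0.01,
    total_exchange_area_cm2 = 5e4)
  phys1$segments$proximal <- TRUE
  drug <- morphine_renal_params(secretion_total = 30)
  drug$secretion <- split_subsegments(30, 1)
  fn <- function(ph) 1 / (1 + 10^(7.9 - ph))
  pa <- 26.3 / fn(7.4) * 1e-6 * 5e4 * 3.6
  c1 <- (7.2 * 0.64 + 30 + pa * fn(7.4) * 0.64) / (3.6 + pa * fn(6.9))
  expect_equal(simulate_renal_clearance(drug, phys1), 3.6 * c1,
               tolerance = 1e-7)
})

test_that("steady-state mass balance holds segment by segment", {
  det <- simulate_renal_clearance(morphine_renal_params(),
                                  kidney_physiology(), detail = TRUE)
  influx <- det$inflow + det$secretion_flux + det$influx_flux
  outflux <- det$outflow + det$reabs_flux
  expect_true(all(abs(influx - outflux) / influx < 1e-6))
})

test_that("renal clearance rises with secretion and unbound fraction", {
  phys <- kidney_physiology()
  clr_sec <- vapply(c(10, 20, 39.3, 60), function(s)
    simulate_renal_clearance(morphine_renal_params(secretion_total = s), phys),
    numeric(1))
  expect_true(all(diff(clr_sec) > 0))
  clr_fu <- vapply(c(0.2, 0.4, 0.64, 0.9), function(fu) {
    d <- morphine_renal_params(); d$fu_p <- fu
    simulate_renal_clearance(d, phys)
  }, numeric(1))
  expect_true(all(diff(clr_fu) > 0))
})

test_that("the disease scaling rule is proportional and monotone", {
  phys <- kidney_physiology()
  drug <- morphine_renal_params()
  adj <- apply_ckd(phys, drug, 60)
  expect_equal(adj$physiology$gfr, 60)
  expect_equal(adj$physiology$segments$flow_out_L_h,
               phys$segments$flow_out_L_h / 2)
  expect_equal(adj$drug$secretion$total, drug$secretion$total / 2)
  ident <- apply_ckd(phys, drug, 120)
  expect_equal(simulate_renal_clearance(ident$drug, ident$physiology),
               simulate_renal_clearance(drug, phys))
  eskd <- apply_ckd(phys, drug, 3)
  expect_equal(eskd$drug$secretion$total, drug$secretion$total * 0.025)
  expect_lt(simulate_renal_clearance(eskd$drug, eskd$physiology),
            simulate_renal_clearance(drug, phys))
  expect_error(apply_ckd(phys, drug, 0), "positive")
  expect_error(apply_ckd(phys, drug, 121), "baseline")
})

test_that("clearance-versus-GFR profiles are monotone and match direct calls", {
  phys <- kidney_physiology()
  drugs <- list(morphine_renal_params(), m6g_renal_params())
  prof <- clr_vs_gfr_profile(drugs, phys, gfr_grid = c(3, 30, 60, 90, 120))
  for (cmp in unique(prof$compound)) {
    cl <- prof$clr_L_per_h[prof$compound == cmp]
    expect_true(all(diff(cl) > 0))
  }
  single <- clr_vs_gfr_profile(morphine_renal_params(), phys, gfr_grid = 120)
  expect_equal(single$clr_L_per_h,
               simulate_renal_clearance(morphine_renal_params(), phys))
  # a filtration-only compound tracks the fu*GFR line
  inert <- renal_drug_params("inert", 0.5, 1, 7.9, 0,
                             split_subsegments(0, 3))
  line <- clr_vs_gfr_profile(inert, phys, gfr_grid = c(30, 60, 120))
  expect_equal(line$clr_L_per_h, 0.5 * 0.06 * c(30, 60, 120),
               tolerance = 1e-8)
})

test_that("exchange-area calibration reproduces its target and is frozen", {
  phys <- kidney_physiology()
  # the shipped default area reproduces the morphine anchor
  expect_equal(simulate_renal_clearance(morphine_renal_params(), phys), 8.24,
               tolerance = 1e-4)
  # calibration from a cold start recovers the same scale
  cold <- kidney_physiology(total_exchange_area_cm2 = 1e5)
  area <- calibrate_exchange_area(morphine_renal_params(), 8.24, cold)
  expect_equal(area, sum(phys$segments$area_cm2), tolerance = 1e-4)
})

test_that("frozen physiology predicts the metabolite and donors within twofold-quality bounds", {
  phys <- kidney_physiology()
  expect_equal(simulate_renal_clearance(m6g_renal_params(), phys), 10.84,
               tolerance = 0.25)
  donors <- mps_donor_summary()
  for (cmp in c("morphine", "M6G")) {
    pred <- predict_donor_clr(cmp, phys = phys)
    ref <- donors$clr_predicted_L_h[donors$compound == cmp]
    expect_true(all(abs(pred$clr_L_per_h / ref - 1) < 0.25))
  }
})
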