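#' Reference compound sheets: morphine and morphine-6-glucuronide
#'
#' Population-level model inputs for the worked example compounds. The
#' permeability and secretion values are the MPS-derived whole-population
#' estimates; distribution coefficients are the optimized tissue:plasma
#' partition set for morphine and a uniform 0.3 (interstitial space) for
#' M6G; morphine hepatic parameters come from the observed systemic
#' clearance after intravenous dosing (83.5 L/h) minus the model-predicted
#' renal clearance, back-calculated to an intrinsic clearance with the
#' well-stirred liver model. M6G hepatic clearance is negligible; it is
#' formed from morphine with a formation fraction of 0.1.
#'
#' @param secretion_total whole-kidney secretion clearance, L/h.
#' @param papp apparent permeability, 1e-6 cm/s.
#' @return [renal_drug_params()] for `*_renal_params()`; a [drug_model()]
#'   for `*_model()`.
#' @name compound-library
NULL

#' @rdname compound-library
#' @export
morphine_renal_params <- function(secretion_total = 39.3, papp = 26.3) {
  renal_drug_params(
    name = "morphine", fu_p = 0.64, blood_plasma_ratio = 1.08,
    pka_base = 7.9, papp = papp,
    secretion = split_subsegments(secretion_total, 3),
    mol_weight = 285.34)
}

#' @rdname compound-library
#' @export
m6g_renal_params <- function(secretion_total = 43.5, papp = 23.8) {
  renal_drug_params(
    name = "M6G", fu_p = 0.89, blood_plasma_ratio = 0.55,
    pka_base = 9.12, papp = papp,
    secretion = split_subsegments(secretion_total, 3),
    mol_weight = 461.46)
}

#' @rdname compound-library
#' @export
morphine_kp <- function() {
  c(adipose = 0.50, bone = 2.07, brain = 1.97, gut = 5.49, heart = 6.79,
    kidney = 5.54, liver = 11.19, lung = 1.77, muscle = 2.50,
    pancreas = 4.19, skin = 0.50, spleen = 6.27)
}

#' @rdname compound-library
#' @export
m6g_kp <- function() {
  tissues <- c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "lung", "muscle", "pancreas", "skin", "spleen")
  stats::setNames(rep(0.3, length(tissues)), tissues)
}

#' Per-donor MPS clearance summary for morphine and M6G
#'
#' Intrinsic active secretion clearance (uL/h per device) and apparent
#' permeability (1e-6 cm/s) measured in devices from three primary
#' proximal-tubule cell donors, together with the renal clearance each
#' donor's inputs predict. Standard deviations are across devices where
#' more than one device was run; `NA` where a single device was measured.
#'
#' @return data.frame with one row per donor x compound.
#' @export
mps_donor_summary <- function() {
  data.frame(
    donor = rep(c("donor1", "donor2", "donor3"), 2),
    compound = rep(c("morphine", "M6G"), each = 3),
    cl_int_sec_uL_h = c(14.1, 1.33, 20.87, 15.6, 1.29, 22.9),
    cl_int_sec_sd = c(11.9, 0.57, NA, 10.5, 1.09, NA),
    papp_1e6_cm_s = c(27.8, 13.9, 42.7, 25.9, 9.74, 41.8),
    papp_sd = c(22.3, NA, NA, 28.5, 11.1, NA),
    clr_predicted_L_h = c(9.69, 4.78, 8.27, 11.6, 7.23, 9.49),
    clr_predicted_sd = c(5.18, 0.61, NA, 3.14, 1.61, NA))
}

#' Predict per-donor renal clearance from the MPS summary table
#'
#' Scales each donor's intrinsic active secretion clearance to the whole
#' kidney, pairs it with the donor's measured permeability, and runs the
#' (frozen) mechanistic kidney model. The compound-level constants
#' (fraction unbound, blood:plasma ratio, pKa) come from the reference
#' sheets.
#'
#' @param compound `"morphine"` or `"M6G"`.
#' @param donors donor summary table, by default [mps_donor_summary()].
#' @param phys a [kidney_physiology()].
#' @param factors a [scaling_factors()].
#' @return data.frame with donor, scaled secretion (L/h) and predicted
#'   renal clearance (L/h).
#' @export
predict_donor_clr <- function(compound = c("morphine", "M6G"),
                              donors = mps_donor_summary(),
                              phys = kidney_physiology(),
                              factors = scaling_factors()) {
  compound <- match.arg(compound)
  base <- if (compound == "morphine") morphine_renal_params()
          else m6g_renal_params()
  d <- donors[donors$compound == compound, ]
  cl_sec <- scale_secretion(d$cl_int_sec_uL_h, factors)
  clr <- vapply(seq_len(nrow(d)), function(i) {
    drug <- base
    drug$papp <- d$papp_1e6_cm_s[i]
    drug$secretion <- split_subsegments(cl_sec[i], 3)
    simulate_renal_clearance(drug, phys)
  }, numeric(1))
  data.frame(donor = d$donor, compound = compound,
             cl_secretion_L_h = cl_sec, clr_L_per_h = clr)
}
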