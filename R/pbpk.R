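#' Reference-human body physiology for the whole-body PBPK model
#'
#' A 70-kg reference table: volumes (L) and blood flows (L/h) for twelve
#' perfusion-limited tissues, arterial/venous blood with a plasma and
#' erythrocyte split, and a lung in series with the cardiac output
#' (360 L/h). Splanchnic outflow (gut, spleen, pancreas) drains into the
#' liver; total hepatic blood flow is 99.7 L/h. Plasma concentrations are
#' sampled either from a peripheral arm vein (flow-weighted venous effluent
#' of muscle, skin and adipose) or from central venous blood.
#'
#' @param cardiac_output total blood flow through the lung, L/h.
#' @param v_plasma plasma volume, L.
#' @param hematocrit erythrocyte volume fraction of blood.
#' @param sampling_site `"arm_vein"` or `"central_venous"`.
#' @return an object of class `body_physiology`.
#' @export
body_physiology <- function(cardiac_output = 360, v_plasma = 3.0,
                            hematocrit = 0.45,
                            sampling_site = c("arm_vein", "central_venous")) {
  sampling_site <- match.arg(sampling_site)
  tissues <- data.frame(
    tissue = c("adipose", "bone", "brain", "gut", "heart", "kidney",
               "liver", "lung", "muscle", "pancreas", "skin", "spleen"),
    volume_L = c(13.5, 10.2, 1.45, 1.65, 0.33, 0.31,
                 1.82, 0.53, 29.0, 0.14, 3.0, 0.15),
    flow_L_h = c(19.5, 19.5, 46.8, 58.5, 15.6, 74.1,
                 25.6, NA, 65.3, 3.9, 19.5, 11.7))
  # lung carries the full cardiac output in series; systemic flows must sum
  # to the cardiac output (liver entry = arterial 25.6 + portal drainage)
  systemic <- tissues$flow_L_h[tissues$tissue != "lung"]
  if (abs(sum(systemic) - cardiac_output) > 1e-6)
    stop("tissue flows must sum to the cardiac output")
  tissues$flow_L_h[tissues$tissue == "lung"] <- cardiac_output
  v_blood <- v_plasma / (1 - hematocrit)
  structure(
    list(tissues = tissues,
         portal = c("gut", "spleen", "pancreas"),
         arm_vein_tissues = c("muscle", "skin", "adipose"),
         cardiac_output = cardiac_output,
         q_hepatic = 25.6 + 58.5 + 11.7 + 3.9,
         v_plasma = v_plasma,
         v_erythrocyte = v_blood - v_plasma,
         v_venous = 0.65 * v_blood,
         v_arterial = 0.35 * v_blood,
         hematocrit = hematocrit,
         sampling_site = sampling_site),
    class = "body_physiology")
}

#' Whole-body drug model
#'
#' Bundles the renal parameter set, tissue partition coefficients and
#' hepatic clearance parameters for one analyte. The hepatic intrinsic
#' clearance drives elimination in a well-stirred liver; a fraction
#' `fm_m6g` of parent hepatic elimination appears as metabolite formation
#' in the liver compartment.
#'
#' @param renal a [renal_drug_params()].
#' @param kp named numeric vector of tissue:plasma partition coefficients
#'   covering the twelve model tissues (`gut` is the gastrointestinal
#'   tract).
#' @param cl_total_iv observed total systemic clearance after intravenous
#'   dosing, L/h (`NA` for a metabolite).
#' @param cl_h hepatic clearance, L/h.
#' @param cl_int_hepatic well-stirred intrinsic hepatic clearance, L/h.
#' @param fm_m6g fraction of hepatic elimination converted to the tracked
#'   metabolite.
#' @return an object of class `drug_model`.
#' @export
drug_model <- function(renal, kp, cl_total_iv = NA_real_, cl_h = 0,
                       cl_int_hepatic = 0, fm_m6g = 0) {
  stopifnot(inherits(renal, "renal_drug_params"))
  if (fm_m6g < 0 || fm_m6g > 1) stop("fm_m6g must be in [0, 1]")
  if (any(kp <= 0)) stop("all partition coefficients must be positive")
  structure(list(renal = renal, kp = kp, cl_total_iv = cl_total_iv,
                 cl_h = cl_h, cl_int_hepatic = cl_int_hepatic,
                 fm_m6g = fm_m6g),
            class = "drug_model")
}

#' @rdname compound-library
#' @param clr model-predicted renal clearance, L/h, used to derive the
#'   hepatic clearance from the observed total clearance.
#' @param cl_total_iv observed total systemic clearance, L/h.
#' @param q_h hepatic blood flow, L/h.
#' @param fm_m6g metabolite formation fraction.
#' @export
morphine_model <- function(clr = NULL, cl_total_iv = 83.5, q_h = 99.7,
                           fm_m6g = 0.1) {
  renal <- morphine_renal_params()
  if (is.null(clr)) clr <- simulate_renal_clearance(renal)
  cl_h <- hepatic_clearance_from_total(cl_total_iv, clr)
  cl_int <- backcalc_intrinsic_hepatic(cl_h, renal$fu_p,
                                       renal$blood_plasma_ratio, q_h)
  drug_model(renal, morphine_kp(), cl_total_iv = cl_total_iv, cl_h = cl_h,
             cl_int_hepatic = cl_int, fm_m6g = fm_m6g)
}

#' @rdname compound-library
#' @export
m6g_model <- function() {
  drug_model(m6g_renal_params(), m6g_kp(), cl_h = 0, cl_int_hepatic = 0,
             fm_m6g = 0)
}

#' Intravenous dose regimen
#'
#' @param amount_mg dose, mg; alternatively give `amount_mg_per_kg`.
#' @param duration_h infusion duration, h; `0` means a bolus (implemented
#'   as a brief loading infusion of 30 s for solver smoothness).
#' @param amount_mg_per_kg weight-based dose, mg/kg.
#' @param subject_mass_kg subject mass, kg.
#' @return an object of class `dose_regimen`.
#' @export
dose_regimen <- function(amount_mg = NULL, duration_h = 0,
                         amount_mg_per_kg = NULL, subject_mass_kg = 70) {
  if (is.null(amount_mg)) {
    if (is.null(amount_mg_per_kg)) stop("give amount_mg or amount_mg_per_kg")
    amount_mg <- amount_mg_per_kg * subject_mass_kg
  }
  if (amount_mg <= 0) stop("dose must be positive")
  structure(list(route = if (duration_h > 0) "iv_infusion" else "iv_bolus",
                 amount_mg = amount_mg, duration_h = duration_h,
                 subject_mass_kg = subject_mass_kg),
            class = "dose_regimen")
}

#' Plasma concentration-time profile
#'
#' @param analyte compound identifier.
#' @param site sampling site label.
#' @param time_h sampling times, h.
#' @param conc_nM plasma concentrations, nM.
#' @param censored optional logical below-LLOQ flags.
#' @param metadata free-form provenance list.
#' @return an object of class `pk_profile`.
#' @export
pk_profile <- function(analyte, site, time_h, conc_nM,
                       censored = rep(FALSE, length(time_h)),
                       metadata = list()) {
  if (any(diff(time_h) <= 0)) stop("time grid must be increasing")
  if (any(conc_nM < -1e-9)) stop("concentrations must be >= 0")
  structure(list(analyte = analyte, site = site,
                 series = data.frame(time_h = time_h,
                                     conc_nM = pmax(conc_nM, 0),
                                     censored = as.logical(censored)),
                 metadata = metadata),
            class = "pk_profile")
}

#' @export
print.pk_profile <- function(x, ...) {
  cat(sprintf("<pk_profile> %s at %s: %d points, t %.3g-%.3g h, Cmax %.4g nM\n",
              x$analyte, x$site, nrow(x$series), min(x$series$time_h),
              max(x$series$time_h), max(x$series$conc_nM)))
  invisible(x)
}

#' Steady-state distribution volume from partition coefficients
#'
#' `Vss = V_plasma + V_ery * E:P + sum(V_t * Kp_t)` referenced to plasma,
#' where the erythrocyte:plasma ratio is implied by the blood:plasma ratio
#' and hematocrit, `E:P = (B/P - (1 - Hct)) / Hct`, floored at zero for
#' compounds excluded from erythrocytes.
#'
#' @param drug a [drug_model()].
#' @param phys a [body_physiology()].
#' @return volume, L (plasma-referenced).
#' @export
compute_vss <- function(drug, phys = body_physiology()) {
  stopifnot(inherits(drug, "drug_model"), inherits(phys, "body_physiology"))
  missing <- setdiff(phys$tissues$tissue, names(drug$kp))
  if (length(missing)) stop("missing Kp for: ", paste(missing, collapse = ", "))
  ep <- max((drug$renal$blood_plasma_ratio - (1 - phys$hematocrit)) /
              phys$hematocrit, 0)
  phys$v_plasma + phys$v_erythrocyte * ep +
    sum(phys$tissues$volume_L * drug$kp[phys$tissues$tissue])
}

#' Hepatic clearance as total minus renal
#'
#' @param cl_total_iv observed total systemic clearance, L/h.
#' @param cl_r renal clearance, L/h, with `0 <= cl_r <= cl_total_iv`.
#' @return hepatic clearance, L/h.
#' @export
hepatic_clearance_from_total <- function(cl_total_iv, cl_r) {
  if (cl_r < 0) stop("cl_r must be >= 0")
  if (cl_r > cl_total_iv) stop("renal clearance exceeds total clearance")
  cl_total_iv - cl_r
}

#' Well-stirred intrinsic hepatic clearance and its forward model
#'
#' Back-calculation: `CL_int = Q_h * CL_h / (fu_b * (Q_h - CL_h))` with
#' `fu_b = fu_p / (B/P)`. The forward well-stirred model
#' `CL_h = Q_h * fu_b * CL_int / (Q_h + fu_b * CL_int)` inverts it exactly.
#'
#' @param cl_h hepatic clearance, L/h (must be below `q_h`).
#' @param cl_int intrinsic hepatic clearance, L/h.
#' @param fu_p fraction unbound in plasma.
#' @param bp blood-to-plasma ratio.
#' @param q_h hepatic blood flow, L/h.
#' @return clearance, L/h.
#' @export
backcalc_intrinsic_hepatic <- function(cl_h, fu_p, bp, q_h = 99.7) {
  if (cl_h < 0) stop("cl_h must be >= 0")
  if (cl_h >= q_h) stop("hepatic extraction at or above 1: cl_h must be < q_h")
  fu_b <- fu_p / bp
  q_h * cl_h / (fu_b * (q_h - cl_h))
}

#' @rdname backcalc_intrinsic_hepatic
#' @export
well_stirred_hepatic <- function(cl_int, fu_p, bp, q_h = 99.7) {
  fu_b <- fu_p / bp
  q_h * fu_b * cl_int / (q_h + fu_b * cl_int)
}

## ---- coupled parent-metabolite ODE system ------------------------------

## state layout per analyte: 12 tissues, arterial, venous, 6 filtrate,
## cumulative urine, cumulative hepatic elimination  (21 states)
pbpk_layout <- function(phys, kidney_phys) {
  nt <- nrow(phys$tissues)
  nf <- nrow(kidney_phys$segments)
  n1 <- nt + 2 + nf + 2
  list(nt = nt, nf = nf, n1 = n1,
       i_tis = seq_len(nt), i_art = nt + 1, i_ven = nt + 2,
       i_fil = nt + 2 + seq_len(nf), i_urine = nt + 2 + nf + 1,
       i_hep = nt + 2 + nf + 2)
}

pbpk_analyte_pars <- function(drug, phys, kidney_phys) {
  k <- kidney_coefficients(drug$renal, kidney_phys)
  list(kp = unname(drug$kp[phys$tissues$tissue]),
       fu_b = drug$renal$fu_p / drug$renal$blood_plasma_ratio,
       cl_int = drug$cl_int_hepatic,
       filt = k$gfr_L_h * drug$renal$fu_p,   # L/h vs arterial plasma
       sec = k$secretion, influx = k$influx,
       reabs = k$reabs, q_fil = k$q_out, v_fil = k$vol,
       fm = drug$fm_m6g)
}

#' Simulate coupled parent-metabolite whole-body pharmacokinetics
#'
#' Integrates the full PBPK system for a parent drug and its metabolite:
#' perfusion-limited tissues, lung in series with the cardiac output, a
#' well-stirred liver eliminating the parent (a fraction of which forms
#' the metabolite in the liver compartment), and the mechanistic kidney
#' model embedded for both analytes. Glomerular and peritubular capillaries
#' are taken at arterial plasma concentration; reabsorbed drug returns with
#' renal venous blood, so the renal clearance realized in the whole-body
#' model matches the standalone kidney model referenced to arterial plasma.
#' Circulating concentrations are plasma-referenced; the blood:plasma ratio
#' enters through the well-stirred liver term.
#'
#' @param parent,metabolite [drug_model()] objects; `NULL` metabolite
#'   simulates the parent alone.
#' @param dose a [dose_regimen()] of the parent.
#' @param phys a [body_physiology()].
#' @param kidney_phys a [kidney_physiology()] (already CKD-adjusted if
#'   simulating kidney disease; its secretion lives in each drug model).
#' @param horizon simulation horizon, h.
#' @param dt output grid step, h.
#' @param rtol,atol solver tolerances (stiff lsoda).
#' @return an object of class `pbpk_sim`: `parent` and `metabolite`
#'   [pk_profile()]s, a `balance` data.frame auditing mass conservation at
#'   every output time, and the raw state matrix.
#' @export
simulate_parent_metabolite <- function(parent, metabolite = NULL,
                                       dose = dose_regimen(10),
                                       phys = body_physiology(),
                                       kidney_phys = kidney_physiology(),
                                       horizon = 24, dt = 0.05,
                                       rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(parent, "drug_model"), inherits(dose, "dose_regimen"))
  if (horizon <= 0) stop("horizon must be positive")
  lay <- pbpk_layout(phys, kidney_phys)
  has_met <- !is.null(metabolite)
  p1 <- pbpk_analyte_pars(parent, phys, kidney_phys)
  p2 <- if (has_met) pbpk_analyte_pars(metabolite, phys, kidney_phys)
  tis <- phys$tissues
  q <- tis$flow_L_h
  v <- tis$volume_L
  i_lung <- which(tis$tissue == "lung")
  i_liver <- which(tis$tissue == "liver")
  i_portal <- which(tis$tissue %in% phys$portal)
  i_sys <- setdiff(seq_len(lay$nt), c(i_lung, i_liver, i_portal))
  q_h <- phys$q_hepatic
  co <- phys$cardiac_output
  dose_nmol <- dose$amount_mg * 1e6 / parent$renal$mol_weight
  inf_dur <- max(dose$duration_h, 1 / 120)  # bolus as a 30-s loading infusion
  inf_rate <- dose_nmol / inf_dur

  analyte_derivs <- function(a, p, formation_liver, t_inf_rate) {
    c_tis <- a[lay$i_tis] / v
    c_out <- c_tis / p$kp
    c_art <- a[lay$i_art] / phys$v_arterial
    c_ven <- a[lay$i_ven] / phys$v_venous
    c_fil <- a[lay$i_fil] / p$v_fil
    da <- numeric(lay$n1)
    # perfusion-limited tissues (lung handled in series below)
    da[lay$i_tis] <- q * (c_art - c_out)
    da[lay$i_tis][i_lung] <- co * (c_ven - c_out[i_lung])
    # liver: arterial + portal inflow, well-stirred elimination at outflow
    elim_hep <- p$cl_int * p$fu_b * c_out[i_liver]
    da[lay$i_tis][i_liver] <- q[i_liver] * c_art +
      sum(q[i_portal] * c_out[i_portal]) - q_h * c_out[i_liver] -
      elim_hep + formation_liver
    # kidney nephron: filtration/secretion/influx from arterial plasma,
    # reabsorption to renal vein
    renal_draw <- (p$filt + sum(p$sec) + sum(p$influx)) * c_art
    inflow_fil <- c(p$filt * c_art, p$q_fil[-lay$nf] * c_fil[-lay$nf])
    da[lay$i_fil] <- inflow_fil + (p$sec + p$influx) * c_art -
      (p$q_fil + p$reabs) * c_fil
    reabs_total <- sum(p$reabs * c_fil)
    da[lay$i_urine] <- p$q_fil[lay$nf] * c_fil[lay$nf]
    da[lay$i_hep] <- elim_hep
    # blood pools
    da[lay$i_art] <- co * c_out[i_lung] - sum(q[-i_lung] * c_art) - renal_draw
    da[lay$i_ven] <- sum(q[i_sys] * c_out[i_sys]) + q_h * c_out[i_liver] -
      co * c_ven + reabs_total + t_inf_rate
    da
  }

  derivs <- function(t, y, parms) {
    y1 <- y[seq_len(lay$n1)]
    rate <- if (t < inf_dur) inf_rate else 0
    d1 <- analyte_derivs(y1, p1, 0, rate)
    if (!has_met) return(list(d1))
    y2 <- y[lay$n1 + seq_len(lay$n1)]
    formed <- p1$fm * p1$cl_int * p1$fu_b *
      (y1[lay$i_tis][i_liver] / v[i_liver] / p1$kp[i_liver])
    d2 <- analyte_derivs(y2, p2, formed, 0)
    list(c(d1, d2))
  }

  n_states <- lay$n1 * (1 + has_met)
  times <- sort(unique(c(seq(0, horizon, by = dt), inf_dur)))
  out <- deSolve::lsoda(y = rep(0, n_states), times = times, func = derivs,
                        parms = NULL, rtol = rtol, atol = atol,
                        maxsteps = 50000)
  if (attr(out, "istate")[1] < 0) stop("PBPK solver failed")
  states <- out[, -1, drop = FALSE]
  if (min(states) < -1e-6 * dose_nmol) stop("negative state in PBPK solution")

  profile_of <- function(block, pars, analyte) {
    conc <- if (phys$sampling_site == "central_venous") {
      block[, lay$i_ven] / phys$v_venous
    } else {
      iw <- match(phys$arm_vein_tissues, tis$tissue)
      wts <- q[iw] / sum(q[iw])
      venous_p <- sweep(block[, lay$i_tis[iw], drop = FALSE], 2,
                        v[iw] * pars$kp[iw], "/")
      as.numeric(venous_p %*% wts)
    }
    pk_profile(analyte = analyte, site = phys$sampling_site,
               time_h = times, conc_nM = pmax(conc, 0),
               metadata = list(dose_mg = dose$amount_mg,
                               duration_h = dose$duration_h,
                               horizon_h = horizon))
  }

  b1 <- states[, seq_len(lay$n1), drop = FALSE]
  parent_prof <- profile_of(b1, p1, parent$renal$name)
  in_body1 <- rowSums(b1[, c(lay$i_tis, lay$i_art, lay$i_ven, lay$i_fil),
                         drop = FALSE])
  dosed <- pmin(times, inf_dur) * inf_rate
  balance <- data.frame(
    time_h = times,
    dosed_nmol = dosed,
    parent_in_body = in_body1,
    parent_urine = b1[, lay$i_urine],
    parent_hepatic = b1[, lay$i_hep])
  balance$parent_rel_error <-
    (balance$parent_in_body + balance$parent_urine + balance$parent_hepatic -
       dosed) / dose_nmol

  met_prof <- NULL
  if (has_met) {
    b2 <- states[, lay$n1 + seq_len(lay$n1), drop = FALSE]
    met_prof <- profile_of(b2, p2, metabolite$renal$name)
    balance$metabolite_in_body <-
      rowSums(b2[, c(lay$i_tis, lay$i_art, lay$i_ven, lay$i_fil),
                 drop = FALSE])
    balance$metabolite_urine <- b2[, lay$i_urine]
    balance$metabolite_formed <- p1$fm * b1[, lay$i_hep]
    balance$metabolite_rel_error <-
      (balance$metabolite_in_body + balance$metabolite_urine +
         b2[, lay$i_hep] - balance$metabolite_formed) /
      pmax(balance$metabolite_formed, 1e-12 * dose_nmol)
  }
  structure(list(parent = parent_prof, metabolite = met_prof,
                 balance = balance, times = times, dose_nmol = dose_nmol,
                 states = states),
            class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %s%s, %d output times to %.3g h, max |mass error| %.2g%%\n",
              x$parent$analyte,
              if (!is.null(x$metabolite)) paste0(" -> ", x$metabolite$analyte) else "",
              length(x$times), max(x$times),
              100 * max(abs(x$balance$parent_rel_error))))
  invisible(x)
}
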