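#' Compound-level inputs to the mechanistic kidney model
#'
#' @param name compound identifier.
#' @param fu_p fraction unbound in plasma, in (0, 1].
#' @param blood_plasma_ratio blood-to-plasma concentration ratio (> 0).
#' @param pka_base basic pKa governing pH partitioning.
#' @param papp apparent transcellular permeability, 1e-6 cm/s, measured at
#'   the assay pH recorded in the physiology (7.4 by default).
#' @param secretion a [split_subsegments()] object: whole-kidney active
#'   secretion clearance allocated across proximal subsegments, L/h.
#' @param mol_weight molecular weight, g/mol (used only at reporting edges).
#' @return an object of class `renal_drug_params`.
#' @export
renal_drug_params <- function(name, fu_p, blood_plasma_ratio, pka_base,
                              papp, secretion, mol_weight = NA_real_) {
  if (fu_p <= 0 || fu_p > 1) stop("fu_p must be in (0, 1]")
  if (blood_plasma_ratio <= 0) stop("blood_plasma_ratio must be positive")
  if (papp < 0) stop("papp must be >= 0")
  stopifnot(inherits(secretion, "secretion_clearance"))
  structure(list(name = name, fu_p = fu_p,
                 blood_plasma_ratio = blood_plasma_ratio,
                 pka_base = pka_base, papp = papp, secretion = secretion,
                 mol_weight = mol_weight),
            class = "renal_drug_params")
}

## Exchange-area scale frozen after one-time calibration against the
## morphine anchor (see scripts/calibrate_physiology.R). Units: cm^2 of
## whole-kidney luminal exchange surface (both kidneys, microvilli included).
.default_exchange_area_cm2 <- 346171.8

#' Default whole-kidney physiology for the mechanistic kidney model
#'
#' Six well-mixed filtrate compartments in series: three proximal
#' subsegments (S1-S3), loop of Henle, distal tubule and collecting duct.
#' Water reabsorption reduces filtrate flow from the GFR (120 mL/min) to
#' 40 mL/min at the end of the proximal tubule (equal steps), 24 mL/min
#' after the loop, 12 mL/min after the distal tubule, and a urine flow of
#' 1.2 mL/min. Filtrate pH acidifies from 7.4 to 6.9 along the proximal
#' tubule, rebounds to 7.4 in the loop, and falls to 6.8 (distal) and 6.3
#' (collecting duct / urine). The exchange-area profile is dominated by the
#' proximal tubule, whose brush-border microvilli carry the vast majority
#' of the luminal membrane surface; the total area is a one-time-calibrated
#' constant (see [calibrate_exchange_area()]).
#'
#' @param gfr glomerular filtration rate, mL/min.
#' @param q_kidney kidney blood flow, L/h.
#' @param plasma_ph systemic plasma pH.
#' @param assay_ph pH at which the in-vitro permeability was measured; the
#'   permeability of the unionized species is recovered as
#'   `papp / fraction_unionized(assay_ph, pka)`.
#' @param total_exchange_area_cm2 whole-kidney luminal exchange area, cm^2.
#' @param area_weights relative area per segment (sums to 1).
#' @param segment_ph filtrate pH per segment.
#' @param flow_out_mL_min filtrate flow leaving each segment, mL/min; the
#'   last entry is the urine flow.
#' @param volume_L luminal volume per segment, L (dynamics only; the steady
#'   state is volume-independent).
#' @return an object of class `kidney_physiology`.
#' @export
kidney_physiology <- function(gfr = 120,
                              q_kidney = 66,
                              plasma_ph = 7.4,
                              assay_ph = 7.4,
                              total_exchange_area_cm2 = .default_exchange_area_cm2,
                              area_weights = c(S1 = 0.45, S2 = 0.35, S3 = 0.18,
                                               LoH = 0.005, DT = 0.005, CD = 0.01),
                              segment_ph = c(7.4, 7.15, 6.9, 7.4, 6.8, 6.3),
                              flow_out_mL_min = c(93.333, 66.667, 40, 24, 12, 1.2),
                              volume_L = c(0.010, 0.008, 0.006, 0.006, 0.003, 0.003)) {
  if (gfr <= 0) stop("gfr must be positive")
  n <- length(flow_out_mL_min)
  stopifnot(length(segment_ph) == n, length(area_weights) == n,
            length(volume_L) == n)
  flow_in <- c(gfr, flow_out_mL_min[-n])
  if (any(flow_out_mL_min > flow_in))
    stop("filtrate flows must be non-increasing (water reabsorption only)")
  if (any(segment_ph < 4.5 | segment_ph > 8))
    stop("segment pH out of physiologic range [4.5, 8]")
  segments <- data.frame(
    name = if (!is.null(names(area_weights))) names(area_weights)
           else paste0("seg", seq_len(n)),
    flow_in_L_h = mL_per_min_to_L_per_h(flow_in),
    flow_out_L_h = mL_per_min_to_L_per_h(flow_out_mL_min),
    ph = segment_ph,
    area_cm2 = total_exchange_area_cm2 * area_weights / sum(area_weights),
    volume_L = volume_L,
    proximal = seq_len(n) <= 3)
  structure(list(gfr = gfr, q_kidney = q_kidney, q_urine = flow_out_mL_min[n],
                 plasma_ph = plasma_ph, assay_ph = assay_ph,
                 segments = segments),
            class = "kidney_physiology")
}

#' @export
print.kidney_physiology <- function(x, ...) {
  cat(sprintf("<kidney_physiology> GFR %.3g mL/min, urine %.3g mL/min, %d segments, area %.3g m^2\n",
              x$gfr, x$q_urine, nrow(x$segments), sum(x$segments$area_cm2) / 1e4))
  print(x$segments, row.names = FALSE)
  invisible(x)
}

## Per-segment rate coefficients for one drug under one physiology; every
## flux in L/h referenced to nM concentrations (-> nmol/h).
## Secretion flux is referenced to total plasma concentration; filtration
## to unbound plasma; passive permeation carries only the unionized
## species, with the measured Papp corrected to the unionized fraction at
## the assay pH.
kidney_coefficients <- function(drug, phys) {
  seg <- phys$segments
  fn_assay <- fraction_unionized(phys$assay_ph, drug$pka_base)
  pa_u <- papp_area_L_per_h(drug$papp / fn_assay, seg$area_cm2)
  sec <- numeric(nrow(seg))
  prox <- which(seg$proximal)
  nsub <- min(drug$secretion$n_subsegments, length(prox))
  if (nsub > 0)
    sec[prox[seq_len(nsub)]] <- drug$secretion$total / drug$secretion$n_subsegments
  list(
    gfr_L_h = mL_per_min_to_L_per_h(phys$gfr),
    q_out = seg$flow_out_L_h,
    vol = seg$volume_L,
    secretion = sec,                                   # L/h vs total plasma
    reabs = pa_u * fraction_unionized(seg$ph, drug$pka_base),   # L/h vs filtrate
    influx = pa_u * fraction_unionized(phys$plasma_ph, drug$pka_base) *
      drug$fu_p                                        # L/h vs total plasma
  )
}

#' Simulate steady-state renal clearance with the mechanistic kidney model
#'
#' Solves the nephron mass-balance ODE system (filtrate compartments in
#' series) to steady state under a constant plasma concentration and
#' returns the renal clearance referenced to plasma,
#' `CL_r = urine flow x urine concentration / C_plasma`. Entry flux is
#' unbound filtration (`GFR * fu_p * C_p`); active secretion delivers
#' `CL_sec,i * C_p` into each proximal subsegment; passive permeation is
#' bidirectional and carried by the unionized species only, so acidic
#' filtrate traps a base in the lumen.
#'
#' Integration uses a stiff solver and steady state is declared when every
#' segment's net flux falls below `tol` relative to its throughput; the
#' run errors rather than returning a non-converged or negative solution.
#'
#' @param drug a [renal_drug_params()].
#' @param phys a [kidney_physiology()].
#' @param c_plasma constant plasma concentration, nM (the clearance is
#'   independent of its value; it sets the simulation scale only).
#' @param detail if `TRUE`, return a list with segment concentrations and
#'   flux diagnostics instead of the bare clearance.
#' @param tol relative steady-state tolerance.
#' @return renal clearance, L/h (plasma-referenced); or a detail list.
#' @export
simulate_renal_clearance <- function(drug, phys = kidney_physiology(),
                                     c_plasma = 1000, detail = FALSE,
                                     tol = 1e-6) {
  stopifnot(inherits(drug, "renal_drug_params"),
            inherits(phys, "kidney_physiology"))
  k <- kidney_coefficients(drug, phys)
  n <- length(k$q_out)
  derivs <- function(t, a, p) {
    conc <- a / k$vol
    inflow <- c(k$gfr_L_h * drug$fu_p * c_plasma,
                k$q_out[-n] * conc[-n])
    da <- inflow + (k$secretion + k$influx) * c_plasma -
      (k$q_out + k$reabs) * conc
    list(da)
  }
  # horizon: several times the slowest segment time constant
  tau <- k$vol / (k$q_out + k$reabs)
  t_end <- 20 * max(tau)
  out <- deSolve::lsoda(y = rep(0, n), times = c(0, t_end / 2, t_end),
                        func = derivs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  a <- unname(out[nrow(out), -1])
  if (any(a < -1e-9)) stop("kidney solver returned negative amounts")
  conc <- pmax(a / k$vol, 0)
  # steady-state check: net flux per segment relative to throughput
  inflow <- c(k$gfr_L_h * drug$fu_p * c_plasma, k$q_out[-n] * conc[-n])
  net <- inflow + (k$secretion + k$influx) * c_plasma -
    (k$q_out + k$reabs) * conc
  thru <- inflow + (k$secretion + k$influx) * c_plasma
  if (max(abs(net) / thru) > tol)
    stop("kidney model failed to reach steady state")
  clr <- k$q_out[n] * conc[n] / c_plasma
  if (!detail) return(clr)
  list(clr_L_h = clr, conc_filtrate_nM = conc,
       inflow = inflow,
       secretion_flux = k$secretion * c_plasma,
       influx_flux = k$influx * c_plasma,
       reabs_flux = k$reabs * conc,
       outflow = k$q_out * conc)
}

#' Apply the chronic kidney disease scaling rule
#'
#' Under the intact nephron hypothesis, nephron functions decline together:
#' GFR, all segment filtrate flows, urine flow, kidney blood flow and the
#' transporter-mediated secretion clearances are scaled by
#' `gfr_target / gfr_baseline`. Exchange areas are left unchanged by
#' default; set `scale_reabsorption = TRUE` to scale the passive
#' reabsorption surface proportionally as well.
#'
#' @param phys a [kidney_physiology()].
#' @param drug a [renal_drug_params()].
#' @param gfr_target target GFR, mL/min, in (0, baseline GFR].
#' @param scale_q_kidney scale kidney blood flow proportionally (default
#'   TRUE).
#' @param scale_reabsorption scale exchange areas proportionally (default
#'   FALSE).
#' @return list with elements `physiology` and `drug`, adjusted.
#' @export
apply_ckd <- function(phys, drug, gfr_target, scale_q_kidney = TRUE,
                      scale_reabsorption = FALSE) {
  stopifnot(inherits(phys, "kidney_physiology"),
            inherits(drug, "renal_drug_params"))
  if (gfr_target <= 0) stop("gfr_target must be positive")
  if (gfr_target > phys$gfr) stop("gfr_target must not exceed the baseline GFR")
  k <- gfr_target / phys$gfr
  phys$gfr <- phys$gfr * k
  phys$q_urine <- phys$q_urine * k
  phys$segments$flow_in_L_h <- phys$segments$flow_in_L_h * k
  phys$segments$flow_out_L_h <- phys$segments$flow_out_L_h * k
  if (scale_q_kidney) phys$q_kidney <- phys$q_kidney * k
  if (scale_reabsorption) phys$segments$area_cm2 <- phys$segments$area_cm2 * k
  drug$secretion <- split_subsegments(drug$secretion$total * k,
                                      drug$secretion$n_subsegments)
  list(physiology = phys, drug = drug)
}

#' Renal clearance across chronic kidney disease stages
#'
#' Sweeps [apply_ckd()] + [simulate_renal_clearance()] over a GFR grid for
#' one or more drugs.
#'
#' @param drugs list of [renal_drug_params()] (or a single one).
#' @param phys baseline [kidney_physiology()].
#' @param gfr_grid GFR values, mL/min, within (0, baseline].
#' @param ... passed to [apply_ckd()].
#' @return data.frame with columns `gfr_mL_min`, `compound`, `clr_L_per_h`.
#' @export
clr_vs_gfr_profile <- function(drugs, phys = kidney_physiology(),
                               gfr_grid = c(3, seq(10, 120, by = 10)), ...) {
  if (inherits(drugs, "renal_drug_params")) drugs <- list(drugs)
  rows <- lapply(drugs, function(drug) {
    clr <- vapply(gfr_grid, function(g) {
      adj <- apply_ckd(phys, drug, g, ...)
      simulate_renal_clearance(adj$drug, adj$physiology)
    }, numeric(1))
    data.frame(gfr_mL_min = gfr_grid, compound = drug$name,
               clr_L_per_h = clr)
  })
  do.call(rbind, rows)
}

#' One-time calibration of the whole-kidney exchange area
#'
#' The luminal exchange-area profile is fixed; the total area is the single
#' free system parameter. It is tuned once so the kidney model reproduces a
#' reference renal clearance (the morphine whole-population value) and then
#' frozen: every other prediction (the metabolite, per-donor values, CKD
#' stages) is made with the frozen physiology.
#'
#' @param drug a [renal_drug_params()] for the calibration compound.
#' @param target_clr reference renal clearance, L/h.
#' @param phys_template physiology whose area will be rescaled.
#' @param interval search interval for the total area, cm^2.
#' @return calibrated total exchange area, cm^2.
#' @export
calibrate_exchange_area <- function(drug,
                                    target_clr,
                                    phys_template = kidney_physiology(),
                                    interval = c(1, 1e8)) {
  seg <- phys_template$segments
  w <- seg$area_cm2 / sum(seg$area_cm2)
  f <- function(total) {
    phys <- phys_template
    phys$segments$area_cm2 <- total * w
    simulate_renal_clearance(drug, phys) - target_clr
  }
  stats::uniroot(f, interval, tol = 1e-6)$root
}
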