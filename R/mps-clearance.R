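#' One channel's effluent concentration-time record
#'
#' The raw in-vitro observable: effluent concentrations collected from one
#' channel (vascular or tubular) of one device under one condition.
#'
#' @param donor donor identifier.
#' @param compound compound identifier.
#' @param condition `"control"` or `"inhibitor"`.
#' @param channel `"vascular"` or `"tubular"`.
#' @param time_h strictly increasing sampling times, h.
#' @param conc_nM non-negative effluent concentrations, nM.
#' @param censored logical flags for values below the assay LLOQ.
#' @param flow_out channel outflow, uL/h.
#' @return an object of class `effluent_series`.
#' @export
effluent_series <- function(donor, compound, condition, channel,
                            time_h, conc_nM, censored = rep(FALSE, length(time_h)),
                            flow_out = 60) {
  condition <- match.arg(condition, c("control", "inhibitor"))
  channel <- match.arg(channel, c("vascular", "tubular"))
  if (length(time_h) != length(conc_nM) || length(time_h) != length(censored))
    stop("time_h, conc_nM and censored must have equal length")
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (any(conc_nM < 0)) stop("concentrations must be >= 0")
  if (flow_out <= 0) stop("flow_out must be positive")
  structure(
    list(donor = donor, compound = compound, condition = condition,
         channel = channel,
         samples = data.frame(time_h = time_h, conc_nM = conc_nM,
                              censored = as.logical(censored)),
         flow_out = flow_out),
    class = "effluent_series")
}

#' @export
print.effluent_series <- function(x, ...) {
  cat(sprintf("<effluent_series> donor %s, %s, %s/%s: %d samples, flow %.3g uL/h\n",
              x$donor, x$compound, x$condition, x$channel,
              nrow(x$samples), x$flow_out))
  invisible(x)
}

#' Dual-channel device geometry
#'
#' The tubule is a cylindrical channel through a collagen matrix; its
#' luminal surface area is `pi * diameter * length` unless overridden.
#' Defaults: 120 um diameter, 1.31 cm length (surface area 0.0493 cm^2),
#' 5000 epithelial cells per device, both channels at 60 uL/h.
#'
#' @param flow_endothelial,flow_tubular channel flows, uL/h.
#' @param tubule_diameter tubule diameter, um.
#' @param tubule_length tubule length, cm.
#' @param surface_area luminal surface area, cm^2; computed from the
#'   cylinder dimensions when `NULL`.
#' @param cells_per_mps epithelial cells per device.
#' @return an object of class `device_geometry`.
#' @export
device_geometry <- function(flow_endothelial = 60, flow_tubular = 60,
                            tubule_diameter = 120, tubule_length = 1.31,
                            surface_area = NULL, cells_per_mps = 5000) {
  if (flow_endothelial <= 0 || flow_tubular <= 0)
    stop("flows must be positive")
  if (is.null(surface_area))
    surface_area <- pi * (tubule_diameter * 1e-4) * tubule_length
  if (surface_area <= 0) stop("surface_area must be positive")
  structure(
    list(flow_endothelial = flow_endothelial, flow_tubular = flow_tubular,
         tubule_diameter = tubule_diameter, tubule_length = tubule_length,
         surface_area = surface_area, cells_per_mps = cells_per_mps),
    class = "device_geometry")
}

#' Steady-state efflux rate and vascular reference concentration
#'
#' Averages non-censored tubular samples inside the steady-state window
#' (default: at and after 6 h of infusion) and multiplies by the tubular
#' outflow to obtain the efflux rate into the lumen. The vascular reference
#' concentration is the window mean of the vascular effluent when supplied,
#' otherwise `nominal_conc`.
#'
#' @param tubular tubular-channel [effluent_series()].
#' @param vascular optional vascular-channel [effluent_series()].
#' @param window_start start of the steady-state window, h.
#' @param nominal_conc fallback dosed concentration, nM.
#' @return list with `efflux_rate` (nmol/h * 1e-6, i.e. nM * uL/h),
#'   `vascular_conc` (nM), `n_samples`, `sd_conc` and the window used.
#' @export
steady_state_efflux <- function(tubular, vascular = NULL, window_start = 6,
                                nominal_conc = 1000) {
  stopifnot(inherits(tubular, "effluent_series"))
  if (tubular$channel != "tubular") stop("first series must be the tubular channel")
  s <- tubular$samples
  keep <- s$time_h >= window_start & !s$censored
  if (sum(s$time_h >= window_start) == 0)
    stop("no samples at or after window_start")
  if (sum(keep) < 2)
    stop("need >= 2 non-censored tubular samples in the steady-state window")
  mean_tub <- mean(s$conc_nM[keep])
  vas_conc <- nominal_conc
  if (!is.null(vascular)) {
    stopifnot(inherits(vascular, "effluent_series"))
    v <- vascular$samples
    vkeep <- v$time_h >= window_start & !v$censored
    if (any(vkeep)) vas_conc <- mean(v$conc_nM[vkeep])
  }
  list(efflux_rate = mean_tub * tubular$flow_out,
       vascular_conc = vas_conc,
       n_samples = sum(keep),
       sd_conc = stats::sd(s$conc_nM[keep]),
       window = c(window_start, max(s$time_h)))
}

#' Apparent clearance from a steady-state efflux rate
#'
#' The apparent clearance across the epithelium is the steady-state efflux
#' rate into the lumen divided by the concentration in the endothelial
#' vessel. Applied per condition: the control arm yields the apparent
#' transport clearance and the inhibitor arm the apparent passive-diffusion
#' clearance.
#'
#' @param efflux_rate efflux rate, nM * uL/h.
#' @param vascular_conc endothelial-vessel concentration, nM (> 0).
#' @return apparent clearance, uL/h.
#' @export
apparent_clearance <- function(efflux_rate, vascular_conc) {
  if (vascular_conc <= 0) stop("vascular concentration must be positive")
  efflux_rate / vascular_conc
}

#' Active secretion clearance by subtraction
#'
#' Active = transport - passive. A negative difference (inhibitor arm above
#' control) has no physical meaning and is clamped to zero with a warning.
#'
#' @param cl_transport,cl_passive apparent (or intrinsic) clearances, same
#'   units, both >= 0.
#' @return clearance difference, clamped at 0.
#' @export
active_from_apparent <- function(cl_transport, cl_passive) {
  if (cl_transport < 0 || cl_passive < 0) stop("clearances must be >= 0")
  d <- cl_transport - cl_passive
  if (d < 0) {
    warning("passive clearance exceeds transport clearance; active clearance clamped to 0")
    d <- 0
  }
  d
}

#' Intrinsic clearance from an apparent clearance
#'
#' In a flow-through device the apparent clearance is attenuated by
#' depletion along the endothelial channel; the intrinsic value is
#' `CL_int = Q * CL_app / (Q - CL_app)` where `Q` is the endothelial flow.
#' It is undefined (flow-limited) when `CL_app >= Q`.
#'
#' @param cl_app apparent clearance, uL/h, with `0 <= cl_app < flow`.
#' @param flow_endothelial endothelial channel flow, uL/h.
#' @return intrinsic clearance, uL/h; always >= `cl_app`.
#' @export
intrinsicize <- function(cl_app, flow_endothelial) {
  if (cl_app < 0) stop("cl_app must be >= 0")
  if (cl_app >= flow_endothelial)
    stop("cl_app at or above the endothelial flow: flow-limited, intrinsic clearance undefined")
  flow_endothelial * cl_app / (flow_endothelial - cl_app)
}

#' Inverse of [intrinsicize()]
#'
#' `CL_app = Q * CL_int / (Q + CL_int)`; useful for round-trip checks and
#' for predicting device readouts from intrinsic values.
#'
#' @param cl_int intrinsic clearance, uL/h (>= 0).
#' @param flow_endothelial endothelial channel flow, uL/h.
#' @return apparent clearance, uL/h.
#' @export
apparentize <- function(cl_int, flow_endothelial) {
  if (cl_int < 0) stop("cl_int must be >= 0")
  flow_endothelial * cl_int / (flow_endothelial + cl_int)
}

#' Apparent transcellular permeability from the intrinsic passive clearance
#'
#' @param cl_int_passive intrinsic passive-diffusion clearance, uL/h.
#' @param geometry a [device_geometry()].
#' @return permeability in 1e-6 cm/s.
#' @export
papp_from_intrinsic <- function(cl_int_passive, geometry) {
  stopifnot(inherits(geometry, "device_geometry"))
  uL_per_h_to_papp(cl_int_passive, geometry$surface_area)
}

#' Reduce one donor's paired effluent series to a clearance set
#'
#' Composes the full in-vitro reduction: steady-state efflux and apparent
#' clearance per arm, active = transport - passive, intrinsicization against
#' the endothelial flow, permeability from the intrinsic passive clearance,
#' and the intrinsic active secretion clearance by subtraction.
#'
#' @param control list with `tubular` and (optionally) `vascular`
#'   [effluent_series()] for the uninhibited arm.
#' @param inhibitor same, for the transporter-inhibited arm.
#' @param geometry a [device_geometry()].
#' @param window_start steady-state window start, h.
#' @param nominal_conc dosed vascular concentration, nM.
#' @param vascular_reference `"inflow"` (default) references clearances to
#'   the dosed concentration, which exactly inverts the steady-state mass
#'   balance used when simulating a device; `"effluent"` references them to
#'   the measured vascular effluent mean, which understates the driving
#'   concentration by the extraction along the vessel. The choice is
#'   recorded in the result.
#' @return an object of class `clearance_set`: apparent and intrinsic
#'   transport/passive/active clearances (uL/h per device), permeability
#'   (1e-6 cm/s) and the steady-state window.
#' @export
reduce_donor <- function(control, inhibitor, geometry = device_geometry(),
                         window_start = 6, nominal_conc = 1000,
                         vascular_reference = c("inflow", "effluent")) {
  vascular_reference <- match.arg(vascular_reference)
  arm <- function(x) {
    vas <- if (vascular_reference == "effluent") x$vascular
    ss <- steady_state_efflux(x$tubular, vas, window_start, nominal_conc)
    apparent_clearance(ss$efflux_rate, ss$vascular_conc)
  }
  cl_app_transport <- arm(control)
  cl_app_passive <- arm(inhibitor)
  cl_app_active <- active_from_apparent(cl_app_transport, cl_app_passive)
  q <- geometry$flow_endothelial
  cl_int_transport <- intrinsicize(cl_app_transport, q)
  cl_int_passive <- intrinsicize(cl_app_passive, q)
  cl_int_active <- active_from_apparent(cl_int_transport, cl_int_passive)
  structure(
    list(donor = control$tubular$donor,
         compound = control$tubular$compound,
         cl_app_transport = cl_app_transport,
         cl_app_passive = cl_app_passive,
         cl_app_active = cl_app_active,
         cl_int_transport = cl_int_transport,
         cl_int_passive = cl_int_passive,
         cl_int_active = cl_int_active,
         papp = papp_from_intrinsic(cl_int_passive, geometry),
         vascular_reference = vascular_reference,
         steady_state_window = c(window_start, max(control$tubular$samples$time_h))),
    class = "clearance_set")
}

#' @export
print.clearance_set <- function(x, ...) {
  cat(sprintf("<clearance_set> donor %s (%s)\n", x$donor, x$compound))
  cat(sprintf("  CL_app  transport %.3g, passive %.3g, active %.3g uL/h\n",
              x$cl_app_transport, x$cl_app_passive, x$cl_app_active))
  cat(sprintf("  CL_int  transport %.3g, passive %.3g, active %.3g uL/h\n",
              x$cl_int_transport, x$cl_int_passive, x$cl_int_active))
  cat(sprintf("  Papp    %.3g x 1e-6 cm/s\n", x$papp))
  invisible(x)
}

#' Two-sample t test for the inhibitor effect on plateau concentrations
#'
#' Classic pooled-variance two-sided Student t test comparing steady-state
#' effluent concentrations with and without the transporter inhibitor
#' cocktail; significance is conventionally declared at p < 0.05.
#'
#' @param control_plateau,inhibitor_plateau numeric vectors of non-censored
#'   plateau concentrations (>= 2 each).
#' @return list with `statistic`, `p_value`, `df`, and `significant`.
#' @export
inhibitor_effect_test <- function(control_plateau, inhibitor_plateau) {
  if (length(control_plateau) < 2 || length(inhibitor_plateau) < 2)
    stop("need >= 2 non-censored samples per arm")
  if (stats::sd(control_plateau) == 0 && stats::sd(inhibitor_plateau) == 0) {
    # degenerate: zero variance in both arms
    eq <- isTRUE(all.equal(mean(control_plateau), mean(inhibitor_plateau)))
    return(list(statistic = if (eq) 0 else Inf,
                p_value = if (eq) 1 else 0,
                df = length(control_plateau) + length(inhibitor_plateau) - 2,
                significant = !eq))
  }
  tt <- stats::t.test(control_plateau, inhibitor_plateau,
                      var.equal = TRUE, alternative = "two.sided")
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), significant = tt$p.value < 0.05)
}
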