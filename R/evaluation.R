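## log-linear interpolation of a concentration-time curve onto new times;
## concentrations are interpolated on the log scale (exponential-like
## decays become piecewise linear), falling back to linear when a bracketing
## value is zero.
interp_conc_loglin <- function(time, conc, new_time) {
  if (any(new_time < min(time)) || any(new_time > max(time)))
    stop("interpolation time outside the simulated range")
  pos <- conc > 0
  vapply(new_time, function(tt) {
    i <- findInterval(tt, time)
    if (time[i] == tt) return(conc[i])
    t0 <- time[i]; t1 <- time[i + 1]
    c0 <- conc[i]; c1 <- conc[i + 1]
    w <- (tt - t0) / (t1 - t0)
    if (c0 > 0 && c1 > 0) exp((1 - w) * log(c0) + w * log(c1))
    else (1 - w) * c0 + w * c1
  }, numeric(1))
}

#' Absolute average fold error between simulated and observed profiles
#'
#' `AAFE = 10 ^ mean(|log10(simulated / observed)|)` over usable points.
#' The simulation is interpolated onto the observed sampling times
#' (log-linearly in concentration); observed points flagged censored or
#' below `lloq` are excluded and counted. AAFE is symmetric in its
#' arguments, >= 1, and invariant to a common concentration unit.
#'
#' @param simulated a [pk_profile()] (dense model output).
#' @param observed a [pk_profile()] of observations.
#' @param lloq optional lower limit of quantification; observed values
#'   below it are excluded in addition to pre-flagged censored points.
#' @return an object of class `aafe_result`: `value`, `n_points`,
#'   `excluded_points`, `passed_twofold`.
#' @export
aafe <- function(simulated, observed, lloq = NULL) {
  stopifnot(inherits(simulated, "pk_profile"), inherits(observed, "pk_profile"))
  obs <- observed$series
  drop <- obs$censored
  if (!is.null(lloq)) drop <- drop | obs$conc_nM < lloq
  usable <- obs[!drop, ]
  if (nrow(usable) == 0) stop("no usable observed points")
  sim <- interp_conc_loglin(simulated$series$time_h, simulated$series$conc_nM,
                            usable$time_h)
  if (any(sim <= 0) || any(usable$conc_nM <= 0))
    stop("zero or negative concentration at a matched point")
  value <- 10^mean(abs(log10(sim / usable$conc_nM)))
  structure(list(value = value, n_points = nrow(usable),
                 excluded_points = sum(drop),
                 passed_twofold = value <= 2),
            class = "aafe_result")
}

#' @export
print.aafe_result <- function(x, ...) {
  cat(sprintf("AAFE = %.3f over %d points (%d excluded): %s the twofold criterion\n",
              x$value, x$n_points, x$excluded_points,
              if (x$passed_twofold) "within" else "OUTSIDE"))
  invisible(x)
}

#' Twofold model-acceptance rule
#'
#' A simulation is acceptable when its absolute average fold error is
#' within twofold (inclusive boundary).
#'
#' @param result an [aafe_result()] from [aafe()], or a bare AAFE value.
#' @return logical.
#' @export
twofold_check <- function(result) {
  value <- if (inherits(result, "aafe_result")) result$value else result
  if (value < 1) stop("AAFE must be >= 1")
  value <= 2
}

#' Non-compartmental analysis of a plasma profile
#'
#' Linear-up/log-down trapezoidal AUC and AUMC with log-linear terminal
#' extrapolation from a fit to the last `n_terminal` positive points.
#' `CL = Dose / AUC`, `MRT = AUMC/AUC - duration/2` (infusion-corrected)
#' and `Vss = CL * MRT`.
#'
#' @param profile a [pk_profile()].
#' @param dose a [dose_regimen()].
#' @param mol_weight molecular weight to convert the dose to nmol.
#' @param n_terminal points in the terminal log-linear fit (>= 3).
#' @return list with `auc_0_inf` (nM*h), `auc_0_t`, `lambda_z` (1/h),
#'   `cl_L_h`, `mrt_h`, `vss_L`.
#' @export
nca <- function(profile, dose, mol_weight, n_terminal = 5) {
  stopifnot(inherits(profile, "pk_profile"), inherits(dose, "dose_regimen"))
  if (n_terminal < 3) stop("need >= 3 terminal points")
  s <- profile$series[profile$series$conc_nM > 0, ]
  t <- s$time_h; conc <- s$conc_nM
  if (length(t) < n_terminal + 2) stop("profile too short for NCA")
  # trapezoids: linear while rising, log while falling
  auc <- aumc <- 0
  for (i in seq_len(length(t) - 1)) {
    dt <- t[i + 1] - t[i]
    c0 <- conc[i]; c1 <- conc[i + 1]
    if (c1 < c0 && c0 > 0 && c1 > 0) {
      k <- log(c0 / c1) / dt
      auc <- auc + (c0 - c1) / k
      aumc <- aumc + (t[i] * c0 - t[i + 1] * c1) / k + (c0 - c1) / k^2
    } else {
      auc <- auc + dt * (c0 + c1) / 2
      aumc <- aumc + dt * (t[i] * c0 + t[i + 1] * c1) / 2
    }
  }
  tail_i <- seq(length(t) - n_terminal + 1, length(t))
  fit <- stats::lm(log(conc[tail_i]) ~ t[tail_i])
  lambda_z <- -unname(stats::coef(fit)[2])
  if (lambda_z <= 0) stop("terminal phase is not declining")
  c_last <- conc[length(t)]; t_last <- t[length(t)]
  auc_inf <- auc + c_last / lambda_z
  aumc_inf <- aumc + c_last * t_last / lambda_z + c_last / lambda_z^2
  dose_nmol <- dose$amount_mg * 1e6 / mol_weight
  cl <- dose_nmol / auc_inf
  mrt <- aumc_inf / auc_inf - max(dose$duration_h, 0) / 2
  list(auc_0_inf = auc_inf, auc_0_t = auc, lambda_z = lambda_z,
       cl_L_h = cl, mrt_h = mrt, vss_L = cl * mrt)
}
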