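#' Cell-number scaling factors for in vitro-in vivo extrapolation
#'
#' Whole-kidney secretion capacity is extrapolated from the per-device
#' intrinsic active secretion clearance by the ratio of proximal tubule
#' cells in the body to cells in the device: 5000 cells per device,
#' 60 million proximal tubular cells per gram of kidney, 300 g kidney per
#' body.
#'
#' @param cells_per_mps epithelial cells per device.
#' @param cells_per_g_kidney proximal tubular cells per gram of kidney.
#' @param kidney_mass total kidney mass, g.
#' @return an object of class `scaling_factors`.
#' @export
scaling_factors <- function(cells_per_mps = 5000,
                            cells_per_g_kidney = 60e6,
                            kidney_mass = 300) {
  if (cells_per_mps <= 0 || cells_per_g_kidney <= 0 || kidney_mass <= 0)
    stop("all scaling factors must be positive")
  structure(list(cells_per_mps = cells_per_mps,
                 cells_per_g_kidney = cells_per_g_kidney,
                 kidney_mass = kidney_mass),
            class = "scaling_factors")
}

#' Scale a per-device intrinsic secretion clearance to the whole kidney
#'
#' `CL_secretion (L/h) = CL_int,active / cells_per_mps * cells_per_g *
#' kidney_mass`, with the uL-to-L conversion. Linear in its input.
#'
#' @param cl_int_active_mps intrinsic active secretion clearance, uL/h per
#'   device (>= 0).
#' @param factors a [scaling_factors()].
#' @return whole-body secretion clearance, L/h.
#' @export
#' @examples
#' scale_secretion(12.1)  # 43.6 L/h
scale_secretion <- function(cl_int_active_mps, factors = scaling_factors()) {
  stopifnot(inherits(factors, "scaling_factors"))
  if (any(cl_int_active_mps < 0)) stop("clearance must be >= 0")
  uL_per_h_to_L_per_h(
    cl_int_active_mps / factors$cells_per_mps *
      factors$cells_per_g_kidney * factors$kidney_mass)
}

#' Allocate a whole-kidney secretion clearance across proximal subsegments
#'
#' Secretion is assigned in equal shares to the proximal subsegments
#' (S1, S2, S3 by default), so `total = per_subsegment * n`.
#'
#' @param total whole-kidney secretion clearance, L/h.
#' @param n number of proximal subsegments (>= 1).
#' @return an object of class `secretion_clearance` with fields `total`,
#'   `per_subsegment`, `n_subsegments`.
#' @export
#' @examples
#' split_subsegments(39.3)  # 13.1 L/h in each of S1-S3
split_subsegments <- function(total, n = 3) {
  if (n < 1) stop("n must be >= 1")
  if (total < 0) stop("total must be >= 0")
  structure(list(total = total, per_subsegment = total / n,
                 n_subsegments = as.integer(n)),
            class = "secretion_clearance")
}
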