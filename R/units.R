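#' Unit conversions used throughout the package
#'
#' In-vitro clearances are carried in uL/h per device exactly as they are
#' measured; whole-body clearances in L/h; permeability in 1e-6 cm/s.
#' All conversions live here so no other file multiplies magic numbers.
#'
#' @param x numeric vector.
#' @return numeric vector in the target unit.
#' @name units
NULL

#' @rdname units
#' @export
uL_per_h_to_L_per_h <- function(x) x * 1e-6

#' @rdname units
#' @export
mL_per_min_to_L_per_h <- function(x) x * 0.06

#' @rdname units
#' @export
L_per_h_to_mL_per_min <- function(x) x / 0.06

#' Convert a clearance in uL/h to an apparent permeability
#'
#' Divides a volumetric clearance by an exchange surface area and reports
#' the result as a velocity in 1e-6 cm/s (1 uL/h = 1e-3 cm^3/h).
#'
#' @param cl_uL_h clearance, uL/h.
#' @param area_cm2 surface area, cm^2.
#' @return permeability in 1e-6 cm/s.
#' @export
uL_per_h_to_papp <- function(cl_uL_h, area_cm2) {
  if (any(area_cm2 <= 0)) stop("surface area must be positive")
  cm3_per_s <- cl_uL_h * 1e-3 / 3600
  (cm3_per_s / area_cm2) / 1e-6
}

#' Permeability-area product in L/h
#'
#' @param papp_1e6 permeability in 1e-6 cm/s.
#' @param area_cm2 area in cm^2.
#' @return volumetric clearance, L/h (1 cm^3/s = 3.6 L/h).
#' @export
papp_area_L_per_h <- function(papp_1e6, area_cm2) {
  papp_1e6 * 1e-6 * area_cm2 * 3.6
}

#' Convert a molar concentration to a mass concentration
#'
#' @param conc_nM concentration in nmol/L.
#' @param mol_weight molecular weight, g/mol.
#' @return concentration in ng/mL.
#' @export
nM_to_ng_per_mL <- function(conc_nM, mol_weight) conc_nM * mol_weight / 1000

#' Fraction unionized of a monoprotic base
#'
#' Henderson-Hasselbalch for a base: the neutral (membrane-permeant) species
#' fraction is `1 / (1 + 10^(pKa - pH))`. At `pH == pKa` exactly half the
#' drug is unionized; in filtrate more acidic than plasma a base is more
#' extensively ionized and therefore trapped in the lumen.
#'
#' @param ph pH of the medium.
#' @param pka_base basic pKa of the compound.
#' @return fraction in (0, 1).
#' @export
#' @examples
#' fraction_unionized(7.4, 7.9)   # morphine in plasma, ~0.24
#' fraction_unionized(6.3, 9.12)  # a strong base in acidic urine, ~1.5e-3
fraction_unionized <- function(ph, pka_base) {
  1 / (1 + 10^(pka_base - ph))
}
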