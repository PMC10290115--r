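#' Hydrostatic suction pressure of the micropipette
#'
#' The suction pressure applied by lowering the water reservoir by
#' \code{delta_h} is rho g delta_h. With the reservoir displacement given
#' in micrometre the result is returned in pN/um^2, which is numerically
#' equal to pascal.
#'
#' @param delta_h reservoir displacement (um).
#' @param rho fluid density (kg/m^3); water, 1000.
#' @param g gravitational acceleration (m/s^2).
#' @return Suction pressure in pN/um^2 (= Pa).
#' @examples
#' suction_pressure(979)  # 9.604 pN/um^2
#' @export
suction_pressure <- function(delta_h, rho = 1000, g = 9.81) {
  if (rho < 0 || g < 0) stop("rho and g must be non-negative")
  stopifnot(is.finite(delta_h))
  rho * g * delta_h * 1e-6
}

#' Pipette cross-section area from inner diameter
#'
#' @param diameter inner diameter (um), > 0.
#' @return Cross-section area pi (d/2)^2 in um^2.
#' @examples
#' cross_section_area(2.1)
#' @export
cross_section_area <- function(diameter) {
  stopifnot(diameter > 0)
  pi * (diameter / 2)^2
}

#' Mechanical work performed against the suction pressure
#'
#' A membrane movement \code{delta_d} against a suction pressure
#' \code{delta_P} over the pipette cross-section \code{A_cross} performs
#' the work W = A delta_d delta_P. In the unit system used here
#' (um^2 x um x pN/um^2 = pN um = 1e-18 J) the result is in attojoule;
#' it is also converted to thermal-energy units using kT = 4.11e-21 J.
#'
#' @param A_cross pipette cross-section area (um^2).
#' @param delta_d membrane movement inside the pipette (um).
#' @param delta_P suction pressure (pN/um^2).
#' @param kBT_J thermal energy (J); default 4.11e-21.
#' @return Named list \code{W_aJ} (attojoule) and \code{W_kBT}.
#' @examples
#' aspiration_work(3.52, 0.82, suction_pressure(979))
#' @export
aspiration_work <- function(A_cross, delta_d, delta_P, kBT_J = 4.11e-21) {
  stopifnot(A_cross >= 0, delta_d >= 0, delta_P >= 0, kBT_J > 0)
  W_aJ <- A_cross * delta_d * delta_P
  list(W_aJ = W_aJ, W_kBT = W_aJ * 1e-18 / kBT_J)
}

#' Membrane photoswitch content implied by an area change
#'
#' Converts a relative membrane-area change into the mole percentage of
#' intercalated surfactant, assuming the surfactant occupies a fixed
#' fraction of a lipid footprint (roughly one half for a single-tail
#' amphiphile): mol% = area% / footprint_ratio.
#'
#' @param rel_area_change_pct relative area change (percent).
#' @param footprint_ratio surfactant-to-lipid footprint ratio, > 0.
#' @return Surfactant content in mol percent.
#' @examples
#' mol_fraction_estimate(2)  # 4 mol%
#' @export
mol_fraction_estimate <- function(rel_area_change_pct, footprint_ratio = 0.5) {
  stopifnot(footprint_ratio > 0)
  rel_area_change_pct / footprint_ratio
}
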