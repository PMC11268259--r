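#' Physical constants shared by the physisorption analysis and the
#' synthetic-isotherm generator
#'
#' A single constants table guarantees that forward-generated isotherms and
#' their BJH/BET analysis use identical thermodynamic assumptions, so
#' round-trip tests close up to discretization error.
#'
#' @format A named list:
#' \describe{
#'   \item{bet_conversion}{m2/g of surface per cm3 STP/g of monolayer
#'     capacity for nitrogen at 77 K (cross-section 16.2 A2, molar STP
#'     volume 22414 cm3/mol): 4.3525.}
#'   \item{n2_cross_section_A2}{Nitrogen molecular cross-section, A2.}
#'   \item{stp_molar_volume_cm3}{Molar volume of an ideal gas at STP,
#'     cm3/mol.}
#'   \item{gas_to_liquid}{Conversion from cm3 STP/g of N2 gas to cm3/g of
#'     liquid nitrogen: 0.0015468.}
#'   \item{kelvin_A}{Kelvin constant for N2 at 77 K: core radius
#'     r_K (A) = 4.14 / log10(1/p).}
#'   \item{hj_a, hj_b}{Harkins-Jura film thickness law parameters:
#'     t(p) (A) = (hj_a / (hj_b - log10 p))^0.5.}
#' }
#' @export
silica_constants <- list(
  bet_conversion       = 4.3525,
  n2_cross_section_A2  = 16.2,
  stp_molar_volume_cm3 = 22414,
  gas_to_liquid        = 0.0015468,
  kelvin_A             = 4.14,
  hj_a                 = 13.99,
  hj_b                 = 0.034
)

#' Harkins-Jura statistical film thickness for nitrogen at 77 K
#'
#' @param p relative pressure(s) in (0, 1)
#' @param constants constants table, see [silica_constants]
#' @return film thickness in Angstrom
#' @export
film_thickness <- function(p, constants = silica_constants) {
  stopifnot(all(p > 0), all(p < 1))
  sqrt(constants$hj_a / (constants$hj_b - log10(p)))
}

#' Kelvin core radius for nitrogen capillary condensation at 77 K
#'
#' Hemispherical-meniscus (desorption) convention: the core of a pore with
#' Kelvin radius r_K empties at relative pressure p.
#'
#' @inheritParams film_thickness
#' @return core radius in Angstrom
#' @export
kelvin_radius <- function(p, constants = silica_constants) {
  stopifnot(all(p > 0), all(p < 1))
  constants$kelvin_A / log10(1 / p)
}
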