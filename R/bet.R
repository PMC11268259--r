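#' BET specific surface area from a sorption isotherm
#'
#' Fits the linearized BET transform p / (q (1 - p)) against p by ordinary
#' least squares over the stated relative-pressure window of the adsorption
#' branch. The monolayer capacity v_m = 1 / (slope + intercept) and the BET
#' constant C = slope / intercept + 1 follow from the regression; the
#' specific surface area is v_m times a single configured conversion
#' constant (nitrogen cross-section times Avogadro's number over the molar
#' STP volume, 4.3525 m2 g-1 per cm3 STP g-1).
#'
#' @param iso a [sorption_isotherm()]
#' @param fit_range numeric length-2, relative-pressure window; default
#'   `c(0.05, 0.30)`. The multilayer theory holds only in this low-pressure
#'   region, so the r-squared of the linearization is reported for audit.
#' @param constants constants table, see [silica_constants]
#' @return object of class `bet_result`: list with `surface_area_m2_g`,
#'   `monolayer_capacity_cm3_g`, `bet_constant_C`, `fit_range`, `r_squared`,
#'   `n_points_used`
#' @export
bet_surface_area <- function(iso, fit_range = c(0.05, 0.30),
                             constants = silica_constants) {
  stopifnot(inherits(iso, "sorption_isotherm"), length(fit_range) == 2)
  ads <- branch_points(iso, "ads")
  keep <- ads$p_rel >= fit_range[1] & ads$p_rel <= fit_range[2]
  p <- ads$p_rel[keep]
  q <- ads$q_cm3stp_g[keep]
  if (length(p) < 3)
    stop("insufficient points: need >= 3 adsorption points in fit range")
  if (any(q <= 0))
    stop("insufficient points: non-positive uptake inside fit range")

  y <- p / (q * (1 - p))
  fit <- stats::lm(y ~ p)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  vm <- 1 / (slope + intercept)
  C <- slope / intercept + 1
  if (!is.finite(vm) || vm <= 0 || !is.finite(C) || C <= 0)
    stop("BET fit invalid in this range: non-positive monolayer capacity or C")

  # r2 of the linearization (squared correlation; avoids summary.lm noise
  # on numerically perfect fits)
  r2 <- stats::cor(y, stats::fitted(fit))^2

  structure(list(
    surface_area_m2_g        = vm * constants$bet_conversion,
    monolayer_capacity_cm3_g = vm,
    bet_constant_C           = C,
    fit_range                = fit_range,
    r_squared                = r2,
    n_points_used            = length(p)
  ), class = "bet_result")
}

#' @export
print.bet_result <- function(x, ...) {
  cat(sprintf("BET surface area: %.1f m2/g (v_m = %.2f cm3 STP/g, C = %.1f)\n",
              x$surface_area_m2_g, x$monolayer_capacity_cm3_g, x$bet_constant_C))
  cat(sprintf("  fit range p/p0 %.3g-%.3g, %d points, r2 = %.6f\n",
              x$fit_range[1], x$fit_range[2], x$n_points_used, x$r_squared))
  invisible(x)
}

#' Total pore volume by the single-point (Gurvich) rule
#'
#' Quantity adsorbed at the highest relative pressure above the threshold,
#' converted from cm3 STP of gas to cm3 of condensed liquid nitrogen.
#'
#' @inheritParams bet_surface_area
#' @param threshold relative pressure above which the isotherm plateau is
#'   read, default 0.98
#' @return total pore volume, cm3 liquid per g
#' @export
total_pore_volume <- function(iso, threshold = 0.98,
                              constants = silica_constants) {
  stopifnot(inherits(iso, "sorption_isotherm"))
  ads <- branch_points(iso, "ads")
  above <- ads[ads$p_rel > threshold, , drop = FALSE]
  if (nrow(above) == 0)
    stop("isotherm does not reach threshold p/p0 > ", threshold)
  q <- above$q_cm3stp_g[which.max(above$p_rel)]
  q * constants$gas_to_liquid
}
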