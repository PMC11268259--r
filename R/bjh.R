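#' BJH pore-size distribution from a sorption isotherm
#'
#' Classic Barrett-Joyner-Halenda stepwise accounting on the desorption
#' branch (default): for each pressure step the volume of gas lost is
#' apportioned between capillary cores emptying (Kelvin equation) and the
#' statistical film thinning on the walls of pores already emptied
#' (Harkins-Jura thickness law), assuming cylindrical pore geometry. Bins
#' are reported as pore diameter = 2 x (Kelvin core radius + film
#' thickness).
#'
#' When both branches are present, the accounting is restricted to the
#' capillary-condensation region, identified as the pressure range where
#' the two branches separate (hysteresis). Outside that region the uptake
#' change is film growth or thinning only, and attributing it to pore cores
#' would inflate the distribution (most visibly for nonporous, film-only
#' isotherms). With a single branch the full pressure range is used.
#'
#' @param iso a [sorption_isotherm()]
#' @param branch `"des"` (default, standard practice for mesoporous silica)
#'   or `"ads"`
#' @param hysteresis_rel_tol branch separation, relative to the maximum
#'   uptake, above which a pressure is considered inside the
#'   capillary-condensation region
#' @param constants constants table, see [silica_constants]
#' @return object of class `pore_size_distribution`: data frame with columns
#'   `diameter_A` (mean pore diameter of the bin), `dV_cm3_g` (incremental
#'   pore volume) and `dVdD` (cm3 g-1 A-1), plus attribute `branch`
#' @export
bjh_distribution <- function(iso, branch = c("des", "ads"),
                             hysteresis_rel_tol = 1e-3,
                             constants = silica_constants) {
  stopifnot(inherits(iso, "sorption_isotherm"))
  branch <- match.arg(branch)
  pts <- branch_points(iso, branch)
  if (nrow(pts) < 5)
    stop("insufficient points: need >= 5 points on the ", branch, " branch")
  # work from high to low pressure
  pts <- pts[order(-pts$p_rel), , drop = FALSE]
  if (any(diff(pts$q_cm3stp_g) > 1e-9 * max(pts$q_cm3stp_g)))
    stop("isotherm not physical: uptake must be nonincreasing toward low pressure")

  other_name <- if (branch == "des") "ads" else "des"
  other <- iso[iso$branch == other_name, , drop = FALSE]
  if (nrow(other) > 1 && max(pts$q_cm3stp_g) > 0) {
    qo <- stats::approx(other$p_rel, other$q_cm3stp_g, xout = pts$p_rel)$y
    hys <- abs(pts$q_cm3stp_g - qo)
    hys[is.na(hys)] <- 0
    inside <- hys > hysteresis_rel_tol * max(pts$q_cm3stp_g)
    if (!any(inside)) {
      psd <- pore_size_distribution(numeric(0), numeric(0))
      attr(psd, "branch") <- branch
      return(psd)
    }
    # extend one point beyond each end so the boundary steps are captured
    i1 <- max(1, min(which(inside)) - 1)
    i2 <- min(nrow(pts), max(which(inside)) + 1)
    pts <- pts[i1:i2, , drop = FALSE]
  }

  p <- pts$p_rel
  qliq <- pts$q_cm3stp_g * constants$gas_to_liquid   # condensed-liquid volume
  t_A <- film_thickness(p, constants)
  rk  <- kelvin_radius(p, constants)
  rp  <- rk + t_A                                     # pore radius at each boundary

  n <- length(p) - 1
  d_bin <- v_bin <- numeric(n)
  r_open <- a_open <- numeric(0)  # radii (A) and wall areas (m2/g) of emptied pores
  for (k in seq_len(n)) {
    dvliq <- qliq[k] - qliq[k + 1]
    dt <- t_A[k] - t_A[k + 1]
    t_bar <- (t_A[k] + t_A[k + 1]) / 2
    rp_bar <- (rp[k] + rp[k + 1]) / 2
    rk_bar <- (rk[k] + rk[k + 1]) / 2
    # film thinning on previously emptied pores; the film sits at radius
    # (r - t), so each wall area is reduced by the factor (r - t)/r
    cfac <- pmax((r_open - t_bar) / r_open, 0)
    v_film <- dt * sum(a_open * cfac) * 1e-4   # A * m2/g -> cm3/g
    vp <- (rp_bar / (rk_bar + dt / 2))^2 * (dvliq - v_film)
    vp <- max(vp, 0)
    d_bin[k] <- 2 * rp_bar
    v_bin[k] <- vp
    # cylindrical wall area of this bin: A [m2/g] = 2 V / r * 1e4
    r_open <- c(r_open, rp_bar)
    a_open <- c(a_open, 2 * vp / rp_bar * 1e4)
  }

  psd <- pore_size_distribution(d_bin, v_bin)
  attr(psd, "branch") <- branch
  psd
}

#' Construct a pore-size distribution
#'
#' @param diameter_A pore diameters, Angstrom, strictly positive and strictly
#'   monotone
#' @param dV_cm3_g incremental pore volume per bin, cm3/g, nonnegative
#' @return object of class `pore_size_distribution`
#' @export
pore_size_distribution <- function(diameter_A, dV_cm3_g) {
  stopifnot(length(diameter_A) == length(dV_cm3_g))
  if (any(diameter_A <= 0)) stop("pore diameters must be strictly positive")
  d <- diff(diameter_A)
  if (length(d) && !(all(d > 0) || all(d < 0)))
    stop("pore diameters must be strictly monotone across bins")
  if (any(dV_cm3_g < 0)) stop("incremental volumes must be >= 0")
  # bin width for the density dV/dD: midpoint spacing
  ord <- order(diameter_A)
  da <- diameter_A[ord]; dv <- dV_cm3_g[ord]
  if (length(da) > 1) {
    edges <- c(da[1] - (da[2] - da[1]) / 2,
               (da[-length(da)] + da[-1]) / 2,
               da[length(da)] + (da[length(da)] - da[length(da) - 1]) / 2)
    width <- diff(edges)
  } else width <- NA_real_
  psd <- data.frame(diameter_A = da, dV_cm3_g = dv, dVdD = dv / width)
  class(psd) <- c("pore_size_distribution", "data.frame")
  psd
}

#' Total BJH pore volume of a distribution
#' @param psd a [pore_size_distribution()]
#' @return cm3/g
#' @export
psd_total_volume <- function(psd) {
  stopifnot(inherits(psd, "pore_size_distribution"))
  sum(psd$dV_cm3_g)
}

#' Modal pore diameter of a distribution (peak of dV/dD)
#' @param psd a [pore_size_distribution()]
#' @return Angstrom
#' @export
psd_mode <- function(psd) {
  stopifnot(inherits(psd, "pore_size_distribution"))
  psd$diameter_A[which.max(psd$dVdD)]
}

#' Average pore diameter of a distribution
#'
#' @param psd a [pore_size_distribution()]
#' @param method `"volume_weighted"` (default): volume-weighted mean
#'   diameter; or `"four_v_over_a"`: 4V/A for cylindrical pores, with
#'   A = sum(4 dV / d) over bins
#' @return Angstrom, with the method recorded as attribute `method`
#' @export
average_pore_diameter <- function(psd, method = c("volume_weighted", "four_v_over_a")) {
  stopifnot(inherits(psd, "pore_size_distribution"))
  method <- match.arg(method)
  vtot <- psd_total_volume(psd)
  if (vtot <= 0) stop("empty distribution: zero total pore volume")
  d <- if (method == "volume_weighted") {
    sum(psd$diameter_A * psd$dV_cm3_g) / vtot
  } else {
    # cylinders: A_i = 4 V_i / d_i (consistent units cancel), 4V/A
    4 * vtot / sum(4 * psd$dV_cm3_g / psd$diameter_A)
  }
  structure(d, method = method)
}

#' Bundle the three headline pore metrics of a carrier
#'
#' @param surface_area_m2_g BET surface area, m2/g
#' @param total_pore_volume_cm3_g total pore volume, cm3/g
#' @param average_pore_diameter_A average pore diameter, Angstrom
#' @param consistency_factor the 4V/A diameter implied by area and volume
#'   must be within this multiplicative factor of the stated average
#'   diameter (checked both ways); default 2 allows for broad distributions
#' @return object of class `pore_metrics`
#' @export
pore_metrics <- function(surface_area_m2_g, total_pore_volume_cm3_g,
                         average_pore_diameter_A, consistency_factor = 2) {
  stopifnot(surface_area_m2_g > 0, total_pore_volume_cm3_g > 0,
            average_pore_diameter_A > 0)
  # 4V/A in A: V [cm3/g] / A [m2/g] * 1e4 gives A
  implied <- 4 * total_pore_volume_cm3_g / surface_area_m2_g * 1e4
  consistent <- implied / average_pore_diameter_A < consistency_factor &&
    average_pore_diameter_A / implied < consistency_factor
  structure(list(surface_area_m2_g = surface_area_m2_g,
                 total_pore_volume_cm3_g = total_pore_volume_cm3_g,
                 average_pore_diameter_A = average_pore_diameter_A,
                 four_v_over_a_A = implied,
                 consistent = consistent),
            class = "pore_metrics")
}

#' Percent reduction of pore metrics between a reference and a sample
#'
#' Computes 100 x (reference - sample) / reference for surface area and pore
#' volume, the standard way to express how much of the porosity a loading
#' step has consumed. Negative values (increases) are allowed and flagged.
#'
#' @param reference,sample [pore_metrics()] for the unloaded reference and
#'   the loaded/treated sample
#' @return list with `surface_area_reduction_pct`,
#'   `pore_volume_reduction_pct`, `increase_flagged`
#' @export
pore_metrics_delta <- function(reference, sample) {
  stopifnot(inherits(reference, "pore_metrics"), inherits(sample, "pore_metrics"))
  if (reference$surface_area_m2_g <= 0 || reference$total_pore_volume_cm3_g <= 0)
    stop("undefined reduction: reference metrics must be strictly positive")
  sa <- 100 * (reference$surface_area_m2_g - sample$surface_area_m2_g) /
    reference$surface_area_m2_g
  pv <- 100 * (reference$total_pore_volume_cm3_g - sample$total_pore_volume_cm3_g) /
    reference$total_pore_volume_cm3_g
  list(surface_area_reduction_pct = sa,
       pore_volume_reduction_pct = pv,
       increase_flagged = sa < 0 || pv < 0)
}
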