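#' Next Generation Impactor stage calibration
#'
#' Archival stage cut-off diameters at the 60 L/min calibration flow and the
#' per-stage flow-scaling exponents of the pharmacopoeial NGI calibration.
#' Effective cut-offs at another flow Q follow
#' D50(Q) = D50(60) x (60/Q)^x. Users may supply their own table to
#' [scale_cutoffs()] and [apsd_reduce()].
#'
#' @format data frame with columns `stage`, `cutoff_60lpm_um`,
#'   `flow_exponent`
#' @export
ngi_stage_table <- data.frame(
  stage = paste0("stage", 1:7),
  cutoff_60lpm_um = c(8.06, 4.46, 2.82, 1.66, 0.94, 0.55, 0.34),
  flow_exponent   = c(0.54, 0.52, 0.50, 0.47, 0.53, 0.60, 0.67),
  stringsAsFactors = FALSE
)

#' Scale impactor stage cut-offs to the run flow rate
#'
#' @param flow_lpm volumetric flow rate through the impactor, L/min; a
#'   warning is issued outside the calibrated 30-100 L/min range
#' @param table stage table, default [ngi_stage_table]
#' @return named numeric vector of effective cut-off diameters, um, in
#'   stage order
#' @export
scale_cutoffs <- function(flow_lpm, table = ngi_stage_table) {
  if (flow_lpm <= 0) stop("flow rate must be positive")
  if (flow_lpm < 30 || flow_lpm > 100)
    warning("flow rate outside the calibrated 30-100 L/min range")
  cuts <- table$cutoff_60lpm_um * (60 / flow_lpm)^table$flow_exponent
  if (any(diff(cuts) >= 0))
    stop("cut-offs must be strictly decreasing down the stage order")
  stats::setNames(cuts, table$stage)
}

#' Construct an impactor run
#'
#' Per-location deposited drug masses for one aerosolization. The sizing
#' locations are stages 1-7 plus the micro-orifice collector (MOC); device,
#' inlet and pre-separator deposits count toward dose bookkeeping but not
#' toward the sized distribution.
#'
#' @param masses_ug named numeric vector with names `device`, `inlet`,
#'   `preseparator`, `stage1`..`stage7`, `moc` (missing locations are taken
#'   as zero); all >= 0
#' @param flow_lpm flow rate, L/min
#' @param total_loaded_dose_ug nominal loaded dose, ug (NA to skip the mass
#'   balance check)
#' @param recovery_factor internal-standard recovery correction applied
#'   multiplicatively to every location before reduction, default 1
#' @param balance_tol acceptable recovered/loaded mass ratio range,
#'   default c(0.75, 1.25)
#' @return object of class `impactor_run`
#' @export
impactor_run <- function(masses_ug, flow_lpm, total_loaded_dose_ug = NA,
                         recovery_factor = 1, balance_tol = c(0.75, 1.25)) {
  locs <- c("device", "inlet", "preseparator", paste0("stage", 1:7), "moc")
  if (is.null(names(masses_ug)) || !all(names(masses_ug) %in% locs))
    stop("masses must be named with locations: ", paste(locs, collapse = ", "))
  if (any(masses_ug < 0)) stop("all masses must be >= 0")
  m <- stats::setNames(numeric(length(locs)), locs)
  m[names(masses_ug)] <- masses_ug * recovery_factor
  balance_ok <- NA
  if (!is.na(total_loaded_dose_ug)) {
    ratio <- sum(m) / total_loaded_dose_ug
    balance_ok <- ratio >= balance_tol[1] && ratio <= balance_tol[2]
  }
  structure(list(masses_ug = m, flow_lpm = flow_lpm,
                 total_loaded_dose_ug = total_loaded_dose_ug,
                 balance_ok = balance_ok),
            class = "impactor_run")
}

#' Read an impactor run from CSV
#'
#' Expected header: `location,mass_ug` with locations
#' `device,inlet,preseparator,stage1..stage7,moc`.
#'
#' @param path path to CSV
#' @param flow_lpm flow rate, L/min
#' @param ... passed to [impactor_run()]
#' @return an `impactor_run`
#' @export
read_impactor_run <- function(path, flow_lpm, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("location", "mass_ug") %in% names(df)))
    stop("NGI CSV must have columns location,mass_ug")
  impactor_run(stats::setNames(df$mass_ug, df$location), flow_lpm, ...)
}

sized_mass <- function(run) {
  run$masses_ug[c(paste0("stage", 1:7), "moc")]
}

#' Cumulative undersize distribution of the impactor-sized mass
#'
#' For each stage cut-off d, the percentage of impactor-sized mass (stages
#' 1-7 + MOC) collected on locations with cut-offs below d, i.e. the mass
#' fraction of particles finer than d.
#'
#' @param run an [impactor_run()]
#' @param cutoffs effective cut-offs from [scale_cutoffs()] (um, stage
#'   order)
#' @return data frame with columns `diameter_um`, `undersize_pct`, ordered
#'   by increasing diameter
#' @export
cumulative_undersize <- function(run, cutoffs = scale_cutoffs(run$flow_lpm)) {
  stopifnot(inherits(run, "impactor_run"))
  sm <- sized_mass(run)
  total <- sum(sm)
  if (total <= 0) stop("zero impactor-sized mass")
  if (sum(sm > 0) < 2) stop("need at least two sizing locations with positive mass")
  stages <- paste0("stage", 1:7)
  # undersize at cutoff_k: everything on stages k+1..7 plus MOC
  under <- vapply(seq_along(stages), function(k) {
    below <- c(stages[seq_along(stages) > k], "moc")
    100 * sum(sm[below]) / total
  }, numeric(1))
  out <- data.frame(diameter_um = unname(cutoffs), undersize_pct = under)
  out[order(out$diameter_um), , drop = FALSE]
}

#' MMAD and GSD from a cumulative undersize table
#'
#' The probit (inverse standard-normal quantile) of the fractional undersize
#' is interpolated linearly against ln(diameter) between the bracketing
#' stages: the mass median aerodynamic diameter is the diameter at probit 0
#' (50% undersize) and the geometric standard deviation is
#' sqrt(d(84.13%) / d(15.87%)). If a quantile is not bracketed by the table
#' the nearest segment is extrapolated and the result flagged.
#'
#' @param undersize data frame from [cumulative_undersize()]
#' @param method `"interpolate"` (default): local linear interpolation
#'   between bracketing points; `"regression"`: global OLS of probit on
#'   ln(diameter) over all informative points
#' @return list with `mmad_um`, `gsd`, `extrapolated` (logical), `r_squared`
#'   (regression mode only)
#' @export
mmad_gsd <- function(undersize, method = c("interpolate", "regression")) {
  method <- match.arg(method)
  u <- undersize[order(undersize$diameter_um), , drop = FALSE]
  frac <- u$undersize_pct / 100
  keep <- frac > 0 & frac < 1
  if (sum(keep) < 2) stop("undersize table has fewer than two informative points")
  z <- stats::qnorm(frac[keep])
  ld <- log(u$diameter_um[keep])

  extrapolated <- FALSE
  d_at <- function(p_target) {
    zt <- stats::qnorm(p_target)
    if (method == "regression") {
      fit <- stats::lm(ld ~ z)
      return(exp(unname(stats::predict(fit, data.frame(z = zt)))))
    }
    if (zt <= min(z) || zt >= max(z)) {
      extrapolated <<- TRUE
      idx <- if (zt <= min(z)) order(z)[1:2] else order(z)[(length(z) - 1):length(z)]
    } else {
      i <- max(which(z <= zt))
      idx <- c(i, i + 1)
    }
    # interpolate ln d linearly in probit
    exp(ld[idx[1]] + (zt - z[idx[1]]) * (ld[idx[2]] - ld[idx[1]]) /
          (z[idx[2]] - z[idx[1]]))
  }

  mmad <- d_at(0.5)
  d84 <- d_at(0.8413)
  d16 <- d_at(0.1587)
  r2 <- stats::cor(z, ld)^2
  list(mmad_um = mmad, gsd = sqrt(d84 / d16),
       extrapolated = extrapolated, r_squared = r2)
}

#' Full aerodynamic data reduction of an impactor run
#'
#' Computes the emitted dose (total recovered minus device retention),
#' delivered-dose and device-retention percentages, the fine particle
#' fraction (mass with aerodynamic diameter below `fpf_diameter_um`,
#' obtained by interpolating the cumulative undersize curve, as a
#' percentage of the emitted dose), and MMAD/GSD.
#'
#' @param run an [impactor_run()]
#' @param table stage table, default [ngi_stage_table]
#' @param fpf_diameter_um fine-particle cut, default 5.0 um
#' @param override_balance proceed even if the mass-balance check failed
#' @param method passed to [mmad_gsd()]
#' @return object of class `apsd_result`: list with `emitted_dose_ug`,
#'   `emitted_dose_pct` (of loaded, NA when loaded dose unknown),
#'   `delivered_dose_pct`, `device_retention_pct`, `fpf_pct`, `mmad_um`,
#'   `gsd`, `mmad_extrapolated`, `undersize` table
#' @export
apsd_reduce <- function(run, table = ngi_stage_table, fpf_diameter_um = 5.0,
                        override_balance = FALSE,
                        method = c("interpolate", "regression")) {
  stopifnot(inherits(run, "impactor_run"))
  if (isFALSE(run$balance_ok) && !override_balance)
    stop("mass balance outside tolerance; pass override_balance = TRUE to proceed")
  m <- run$masses_ug
  total <- sum(m)
  emitted <- total - m[["device"]]
  if (emitted <= 0) stop("emitted dose is zero: all mass retained in the device")
  retention_pct <- 100 * m[["device"]] / total
  delivered_pct <- 100 - retention_pct

  cuts <- scale_cutoffs(run$flow_lpm, table)
  under <- cumulative_undersize(run, cuts)
  mg <- mmad_gsd(under, method = method)

  # undersize fraction at the FPF cut, interpolated in (probit, ln d) space
  frac <- under$undersize_pct / 100
  keep <- frac > 0 & frac < 1
  z <- stats::qnorm(frac[keep]); ld <- log(under$diameter_um[keep])
  lt <- log(fpf_diameter_um)
  z_at <- if (lt <= min(ld)) {
    idx <- order(ld)[1:2]
    z[idx[1]] + (lt - ld[idx[1]]) * (z[idx[2]] - z[idx[1]]) / (ld[idx[2]] - ld[idx[1]])
  } else if (lt >= max(ld)) {
    idx <- order(ld)[(length(ld) - 1):length(ld)]
    z[idx[1]] + (lt - ld[idx[1]]) * (z[idx[2]] - z[idx[1]]) / (ld[idx[2]] - ld[idx[1]])
  } else {
    stats::approx(ld, z, xout = lt)$y
  }
  under_frac_at_cut <- stats::pnorm(z_at)
  fine_mass <- under_frac_at_cut * sum(sized_mass(run))
  fpf <- 100 * fine_mass / emitted

  structure(list(
    emitted_dose_ug = unname(emitted),
    emitted_dose_pct = if (is.na(run$total_loaded_dose_ug)) NA_real_ else
      100 * unname(emitted) / run$total_loaded_dose_ug,
    delivered_dose_pct = unname(delivered_pct),
    device_retention_pct = unname(retention_pct),
    fpf_pct = unname(fpf),
    mmad_um = mg$mmad_um,
    gsd = mg$gsd,
    mmad_extrapolated = mg$extrapolated,
    undersize = under
  ), class = "apsd_result")
}

#' @export
print.apsd_result <- function(x, ...) {
  cat(sprintf("APSD reduction: FPF = %.2f%%, MMAD = %.2f um, GSD = %.2f\n",
              x$fpf_pct, x$mmad_um, x$gsd))
  cat(sprintf("  device retention %.2f%%, delivered dose %.2f%%, emitted %.1f ug\n",
              x$device_retention_pct, x$delivered_dose_pct, x$emitted_dose_ug))
  invisible(x)
}
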