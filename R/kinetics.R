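#' Construct a timed release series with withdrawal/replacement bookkeeping
#'
#' @param time_h sampling times, h, strictly increasing
#' @param conc_mg_g measured protein concentration at each sampling, mg per
#'   g of solution
#' @param withdrawn_g mass of solution withdrawn at each sampling, g
#' @param replaced_g mass of fresh medium replaced after each sampling, g
#' @param vessel_mass_g mass of solution in the vessel, g
#' @param omega_lys protein weight fraction of the dry powder, in (0, 1)
#' @param sample_mass_mg mass of dry powder placed in the vessel, mg
#' @return object of class `release_series`
#' @export
release_series <- function(time_h, conc_mg_g, withdrawn_g, replaced_g,
                           vessel_mass_g, omega_lys, sample_mass_mg) {
  stopifnot(length(time_h) == length(conc_mg_g),
            length(time_h) == length(withdrawn_g),
            length(time_h) == length(replaced_g))
  if (any(diff(time_h) <= 0)) stop("times must be strictly increasing")
  if (any(conc_mg_g < 0)) stop("concentrations must be >= 0")
  if (any(withdrawn_g > vessel_mass_g)) stop("withdrawn mass exceeds vessel mass")
  if (omega_lys <= 0 || omega_lys >= 1) stop("omega_lys must be in (0, 1)")
  if (sample_mass_mg <= 0) stop("sample mass must be positive")
  structure(list(
    schedule = data.frame(time_h = time_h, conc_mg_g = conc_mg_g,
                          withdrawn_g = withdrawn_g, replaced_g = replaced_g),
    vessel_mass_g = vessel_mass_g, omega_lys = omega_lys,
    sample_mass_mg = sample_mass_mg
  ), class = "release_series")
}

#' Read a release series from CSV
#'
#' Expected header: `time_h,conc_mg_g,withdrawn_g,replaced_g`.
#' @param path path to CSV
#' @inheritParams release_series
#' @return a `release_series`
#' @export
read_release_series <- function(path, vessel_mass_g, omega_lys, sample_mass_mg) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("time_h", "conc_mg_g", "withdrawn_g", "replaced_g")
  if (!all(req %in% names(df)))
    stop("release CSV must have columns: ", paste(req, collapse = ", "))
  release_series(df$time_h, df$conc_mg_g, df$withdrawn_g, df$replaced_g,
                 vessel_mass_g, omega_lys, sample_mass_mg)
}

#' Per-interval released weight fractions
#'
#' Two bookkeeping conventions for a withdrawal/replacement schedule:
#' \describe{
#'   \item{`as_printed`}{the literal interval formula
#'     w_i = C_i m_vessel / (omega_lys m_sample): each sampling's measured
#'     concentration times the total solution mass, normalized by the loaded
#'     protein mass. Protein left in the vessel from earlier intervals is
#'     counted again, so the running sum can overshoot when release is
#'     incremental between samplings.}
#'   \item{`carryover_corrected`}{the newly released mass per interval is
#'     m_i = C_i m_vessel - C_(i-1) (m_vessel - withdrawn_(i-1)): the
#'     previous interval's residual, diluted by medium replacement, is
#'     subtracted before normalizing. Negative corrected masses (measurement
#'     noise) are floored at zero and flagged.}
#' }
#' The two modes agree when only one interval exists or nothing is
#' withdrawn... provided no protein remains between samplings; they always
#' agree on the first interval.
#'
#' @param series a [release_series()]
#' @param mode `"as_printed"` (default) or `"carryover_corrected"`
#' @return list of class `release_result`: `interval_fractions`,
#'   `cumulative_fractions`, `mode`, `n_floored`
#' @export
interval_release <- function(series, mode = c("as_printed", "carryover_corrected")) {
  stopifnot(inherits(series, "release_series"))
  mode <- match.arg(mode)
  sch <- series$schedule
  m_loaded <- series$omega_lys * series$sample_mass_mg / 1000  # g
  mv <- series$vessel_mass_g
  n_floored <- 0
  if (mode == "as_printed") {
    # C [mg/g] * m [g] = mg -> g
    m_rel <- sch$conc_mg_g * mv / 1000
  } else {
    c_prev <- c(0, sch$conc_mg_g[-nrow(sch)])
    w_prev <- c(0, sch$withdrawn_g[-nrow(sch)])
    m_rel <- (sch$conc_mg_g * mv - c_prev * (mv - w_prev)) / 1000
    n_floored <- sum(m_rel < 0)
    m_rel <- pmax(m_rel, 0)
  }
  frac <- m_rel / m_loaded
  structure(list(interval_fractions = frac,
                 cumulative_fractions = cumsum(frac),
                 time_h = sch$time_h, mode = mode, n_floored = n_floored),
            class = "release_result")
}

#' Cumulative release as the running sum of interval fractions
#'
#' @param fractions numeric vector of per-interval released fractions
#' @return numeric vector of cumulative fractions
#' @export
cumulative_release <- function(fractions) {
  stopifnot(all(is.finite(fractions)))
  cumsum(fractions)
}

#' Percentage of silica dissolved from timed Si concentrations
#'
#' The initial theoretical Si concentration is the particle dose times the
#' Si mass fraction of the carrier; the percent dissolved at each time is
#' the measured Si concentration relative to that value.
#'
#' @param si_mg_L measured Si concentrations, mg/L
#' @param dose_mg_L particle dose concentration, mg/L
#' @param si_mass_fraction Si mass fraction of the carrier; default
#'   28.08/60.08 = 0.4674 from the Si and SiO2 molar masses (assumes the
#'   carrier is pure SiO2)
#' @return percentages, same length as `si_mg_L`
#' @export
si_percent_dissolved <- function(si_mg_L, dose_mg_L,
                                 si_mass_fraction = 28.08 / 60.08) {
  if (dose_mg_L <= 0) stop("particle dose must be positive")
  stopifnot(all(si_mg_L >= 0), si_mass_fraction > 0, si_mass_fraction <= 1)
  100 * si_mg_L / (dose_mg_L * si_mass_fraction)
}

#' Time to 50% dissolution from the early linear region
#'
#' Ordinary least-squares line through all (time, percent) points inside the
#' stated window; T50 is where the fitted line crosses 50%.
#'
#' @param time_h times, h
#' @param percent percent dissolved at each time
#' @param window length-2 time interval treated as the linear region,
#'   default c(0, 8) h
#' @return T50 in h
#' @export
t50_interpolate <- function(time_h, percent, window = c(0, 8)) {
  keep <- time_h >= window[1] & time_h <= window[2]
  if (sum(keep) < 2) stop("need >= 2 points inside the linear window")
  fit <- stats::lm(percent[keep] ~ time_h[keep])
  slope <- unname(stats::coef(fit)[2]); icpt <- unname(stats::coef(fit)[1])
  if (slope <= 0) stop("no dissolution trend: nonpositive slope in window")
  (50 - icpt) / slope
}

#' Remaining enzymatic activity ratio
#'
#' @param sample_activity activity of the released protein, units/mL
#' @param reference_activity activity of the untreated reference at the same
#'   concentration, units/mL
#' @return percent of the reference activity
#' @export
activity_ratio <- function(sample_activity, reference_activity) {
  if (reference_activity <= 0) stop("reference activity must be positive")
  100 * sample_activity / reference_activity
}

#' Normalize raw MTT absorbances to percent viability
#'
#' @param raw_absorbance absorbance of treated wells
#' @param untreated_absorbance mean absorbance of untreated (negative
#'   control) wells
#' @param blank_absorbance blank absorbance
#' @return percent viability
#' @export
normalize_viability <- function(raw_absorbance, untreated_absorbance,
                                blank_absorbance = 0) {
  if (untreated_absorbance <= blank_absorbance)
    stop("untreated absorbance must exceed blank")
  100 * (raw_absorbance - blank_absorbance) /
    (untreated_absorbance - blank_absorbance)
}

#' Four-parameter logistic dose-response fit
#'
#' Nonlinear least squares of y = d + (a - d) / (1 + (x / c)^b) with upper
#' asymptote a, lower asymptote d, inflection concentration c and Hill
#' slope b. When the responses never depart from the upper asymptote by
#' more than the stated noise band across the tested range, the inflection
#' lies beyond the range and `ic50_beyond_range` is set instead of trusting
#' the unidentifiable estimate.
#'
#' @param conc concentrations (>= 5 distinct levels); zero concentrations
#'   are not allowed in the power-law form
#' @param response responses, e.g. normalized viability percent
#' @param flat_tol departure from the plateau (same units as response)
#'   below which the curve is considered flat, default 10
#' @return object of class `four_pl_fit`: list with `upper`, `lower`,
#'   `inflection`, `hill`, `se`, `rss`, `ic50_beyond_range`
#' @export
fit_4pl <- function(conc, response, flat_tol = 10) {
  stopifnot(length(conc) == length(response))
  if (length(unique(conc)) < 5) stop("need >= 5 concentration levels")
  if (any(conc <= 0)) stop("concentrations must be strictly positive")

  upper0 <- max(response); lower0 <- min(response)
  flat <- (upper0 - lower0) <= flat_tol
  if (flat) {
    return(structure(list(upper = mean(response), lower = NA_real_,
                          inflection = NA_real_, hill = NA_real_,
                          se = NULL, rss = sum((response - mean(response))^2),
                          ic50_beyond_range = TRUE),
                     class = "four_pl_fit"))
  }
  half <- (upper0 + lower0) / 2
  c0 <- conc[which.min(abs(response - half))]
  dat <- data.frame(x = conc, y = response)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ d + (a - d) / (1 + (x / cc)^b), data = dat,
                      start = list(a = upper0, d = lower0, cc = c0, b = 1),
                      lower = c(-Inf, -Inf, 1e-12, -50), upper = c(Inf, Inf, Inf, 50),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) stop("fit failed: ", conditionMessage(e)))
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 4))
  beyond <- est[["cc"]] > max(conc) || est[["cc"]] < min(conc)
  structure(list(upper = est[["a"]], lower = est[["d"]],
                 inflection = est[["cc"]], hill = est[["b"]],
                 se = se, rss = sum(stats::resid(fit)^2),
                 ic50_beyond_range = beyond),
            class = "four_pl_fit")
}
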