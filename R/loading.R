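#' Protein loading from supernatant depletion (indirect mass balance)
#'
#' The amount of protein adsorbed is the difference between initial and
#' equilibrium supernatant concentration times the mass of solution, divided
#' by the sorbent mass. Concentrations are mass fractions (mg protein per g
#' of solution); aqueous buffer density is taken as 1 g/mL when converting
#' from mg/mL.
#'
#' @param c0 initial concentration, mg protein per g solution
#' @param c_eq equilibrium (supernatant) concentration, mg/g
#' @param solution_mass_g mass of solution, g
#' @param sorbent_mass_mg mass of sorbent, mg
#' @param loq quantification limit on the depletion `c0 - c_eq` (mg/g);
#'   depletions with magnitude below `loq` are reported as zero loading with
#'   `below_loq = TRUE` rather than dropped
#' @param tol tolerance for apparent negative adsorption (fraction of c0)
#' @return list with `loading_mg_mg` and logical `below_loq`
#' @export
loading_from_supernatant <- function(c0, c_eq, solution_mass_g, sorbent_mass_mg,
                                     loq = 0, tol = 0.02) {
  if (sorbent_mass_mg <= 0) stop("sorbent mass must be positive")
  depletion <- c0 - c_eq
  if (depletion < -tol * c0)
    stop("negative adsorption: equilibrium concentration exceeds initial beyond tolerance")
  if (abs(depletion) < loq)
    return(list(loading_mg_mg = 0, below_loq = TRUE))
  depletion <- max(depletion, 0)
  list(loading_mg_mg = depletion * solution_mass_g / sorbent_mass_mg,
       below_loq = FALSE)
}

#' Langmuir adsorption-isotherm fit
#'
#' Nonlinear least squares of the Langmuir model
#' q = q_max K c / (1 + K c) against (equilibrium concentration, loading)
#' pairs, in the nonlinear form rather than a linearizing transform so the
#' error structure of the measurements is not distorted. Initialization:
#' q_max from the maximum observed loading, K from the concentration at
#' half-maximal loading.
#'
#' @param c_eq equilibrium concentrations, mg per g solution
#' @param loading loadings, mg protein per mg sorbent
#' @param weighting `"relative"` (default): inverse-variance weights for
#'   proportional measurement error (weights 1/loading^2), appropriate for
#'   spectrophotometric quantification whose error scales with the signal;
#'   `"none"`: ordinary unweighted least squares
#' @return object of class `langmuir_fit`: list with `q_max`, `affinity_K`,
#'   `se` (named standard errors), `rss`, `plateau_sampled` (FALSE flags
#'   that the data never approach saturation so q_max is an extrapolation),
#'   and the `fit` object
#' @export
fit_langmuir <- function(c_eq, loading, weighting = c("relative", "none")) {
  stopifnot(length(c_eq) == length(loading))
  weighting <- match.arg(weighting)
  if (length(c_eq) < 4)
    stop("need >= 4 records spanning low and plateau concentrations")
  q_init <- max(loading)
  half <- c_eq[which.min(abs(loading - q_init / 2))]
  k_init <- if (half > 0) 1 / half else 1
  w <- if (weighting == "relative")
    1 / pmax(loading, 1e-3 * max(loading))^2 else rep(1, length(loading))
  dat <- data.frame(c = c_eq, q = loading, w = w)
  fit <- tryCatch(
    minpack.lm::nlsLM(q ~ qmax * K * c / (1 + K * c), data = dat,
                      start = list(qmax = q_init, K = k_init),
                      weights = w, lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failed: ", conditionMessage(e)))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  # plateau considered sampled if the largest loading reaches 80% of q_max
  plateau <- max(loading) >= 0.8 * est[["qmax"]]
  structure(list(q_max = est[["qmax"]], affinity_K = est[["K"]],
                 se = c(q_max = unname(se["qmax"]), affinity_K = unname(se["K"])),
                 rss = sum(stats::resid(fit)^2),
                 plateau_sampled = plateau, fit = fit),
            class = "langmuir_fit")
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("Langmuir fit: q_max = %.4g +/- %.2g mg/mg, K = %.4g +/- %.2g g/mg\n",
              x$q_max, x$se["q_max"], x$affinity_K, x$se["affinity_K"]))
  if (!x$plateau_sampled) cat("  warning: plateau not sampled; q_max is extrapolated\n")
  invisible(x)
}

#' Predict loading from a Langmuir fit
#' @param object a `langmuir_fit`
#' @param c_eq concentrations, mg/g
#' @param ... unused
#' @return predicted loadings, mg/mg
#' @export
predict.langmuir_fit <- function(object, c_eq, ...) {
  object$q_max * object$affinity_K * c_eq / (1 + object$affinity_K * c_eq)
}

#' Theoretical maximum pore-filling capacity of a mesoporous carrier
#'
#' Assumes every pore is completely filled with protein packed at the random
#' close-packing fraction of ellipsoids: m_protein = rho * phi * V_pore per
#' gram of carrier.
#'
#' @param v_pore_cm3_g pore volume of the unloaded carrier, cm3/g
#' @param rho_protein_g_cm3 protein density, g/cm3 (default 1.4, lysozyme)
#' @param packing_fraction phi in (0, 1], default 0.74 (random close packing
#'   of ellipsoids)
#' @return g protein per g carrier
#' @export
max_loading_capacity <- function(v_pore_cm3_g, rho_protein_g_cm3 = 1.4,
                                 packing_fraction = 0.74) {
  stopifnot(v_pore_cm3_g >= 0, rho_protein_g_cm3 > 0,
            packing_fraction >= 0, packing_fraction <= 1)
  rho_protein_g_cm3 * packing_fraction * v_pore_cm3_g
}

#' Achieved loading inferred from the measured pore-volume reduction
#'
#' The loaded composite's pore volume is measured per gram of composite
#' (carrier + protein), so for 1 g of carrier
#' V_loaded = (V_unloaded - m/rho) / (1 + m). Inverting for the protein mass
#' m gives m = (V_unloaded - V_loaded) / (V_loaded + 1/rho).
#'
#' The "unloaded" reference should be the carrier state against which the
#' fill is judged; when buffer alone also occupies pore volume, the
#' buffer-treated placebo is the appropriate baseline and both volumes are
#' therefore taken explicitly.
#'
#' @param v_unloaded_cm3_g pore volume of the reference (unloaded or
#'   placebo-treated) carrier, cm3 per g carrier
#' @param v_loaded_cm3_g pore volume of the loaded composite, cm3 per g
#'   composite
#' @param rho_protein_g_cm3 protein density, g/cm3
#' @return g protein per g carrier
#' @export
loading_from_pore_reduction <- function(v_unloaded_cm3_g, v_loaded_cm3_g,
                                        rho_protein_g_cm3 = 1.4) {
  stopifnot(rho_protein_g_cm3 > 0, v_unloaded_cm3_g >= 0, v_loaded_cm3_g >= 0)
  if (v_loaded_cm3_g > v_unloaded_cm3_g)
    stop("negative apparent loading: loaded pore volume exceeds reference")
  (v_unloaded_cm3_g - v_loaded_cm3_g) / (v_loaded_cm3_g + 1 / rho_protein_g_cm3)
}

#' Read adsorption records from CSV
#'
#' Expected header:
#' `c0_mg_g,ceq_mg_g,solution_mass_g,sorbent_mass_mg,ionic_strength_mM`.
#' A `loading_mg_mg` column is computed from the mass balance.
#'
#' @param path path to CSV
#' @param ... passed to [loading_from_supernatant()]
#' @return data frame of records with computed loadings
#' @export
read_adsorption_records <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("c0_mg_g", "ceq_mg_g", "solution_mass_g", "sorbent_mass_mg")
  if (!all(req %in% names(df)))
    stop("adsorption CSV must have columns: ", paste(req, collapse = ", "))
  res <- mapply(function(c0, ce, sm, so) {
    r <- loading_from_supernatant(c0, ce, sm, so, ...)
    c(r$loading_mg_mg, r$below_loq)
  }, df$c0_mg_g, df$ceq_mg_g, df$solution_mass_g, df$sorbent_mass_mg)
  df$loading_mg_mg <- res[1, ]
  df$below_loq <- as.logical(res[2, ])
  df
}
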