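#' @title Synthetic-data generators
#' @description Every input the pipeline consumes can be generated with
#'   known ground truth and a fixed seed, so each analysis stage is testable
#'   without instrument data. Generators share the physical constants of the
#'   analysis modules through [silica_constants], which makes round-trips
#'   (generate, then analyze) close up to discretization error. Each
#'   generated object carries its truth parameters in the `truth` attribute.
#' @name synthetic
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

mult_noise <- function(x, sd) {
  if (sd <= 0) return(x)
  x * (1 + stats::rnorm(length(x), 0, sd))
}

#' Generate a nitrogen sorption isotherm from a known pore-size distribution
#'
#' Forward Kelvin-plus-film model mirroring the BJH assumptions: at each
#' relative pressure, the quantity adsorbed is the condensed liquid in pores
#' whose cores have filled, plus the statistical film on the walls of
#' unfilled pores and on any external surface. Desorption follows the
#' hemispherical-meniscus Kelvin radius; adsorption condenses at the
#' cylindrical-meniscus radius (half the Kelvin radius), which produces the
#' physical hysteresis direction.
#'
#' @param median_A median of the log-normal pore-volume distribution over
#'   pore diameter, Angstrom
#' @param gsd_g geometric standard deviation of the distribution (> 1)
#' @param total_volume_cm3_g total pore volume, cm3/g
#' @param external_area_m2_g external (non-pore) surface area carrying only
#'   a film, m2/g; default 0
#' @param n_pressure number of pressure points per branch
#' @param p_range relative-pressure range of the simulated isotherm
#' @param n_bins number of pore-diameter bins used to discretize the
#'   distribution
#' @param noise_sd multiplicative Gaussian noise on the uptake, default 0
#' @param seed RNG seed (only used when `noise_sd > 0`)
#' @return a [sorption_isotherm()] with attribute `truth` (list of the
#'   generator parameters)
#' @export
gen_isotherm <- function(median_A, gsd_g, total_volume_cm3_g,
                         external_area_m2_g = 0,
                         n_pressure = 80, p_range = c(0.05, 0.995),
                         n_bins = 400, noise_sd = 0, seed = NULL) {
  stopifnot(median_A > 0, gsd_g > 1, total_volume_cm3_g >= 0)
  mu <- log(median_A); sg <- log(gsd_g)
  qs <- seq(stats::qlnorm(0.001, mu, sg), stats::qlnorm(0.999, mu, sg),
            length.out = n_bins + 1)
  d_i <- (qs[-1] + qs[-(n_bins + 1)]) / 2
  v_i <- total_volume_cm3_g *
    diff(stats::plnorm(qs, mu, sg)) / diff(stats::plnorm(range(qs), mu, sg))
  r_i <- d_i / 2
  # cylindrical wall area per bin, m2/g
  a_i <- 4 * v_i / d_i * 1e4

  uptake <- function(p, branch) {
    t_A <- film_thickness(p)
    rk <- kelvin_radius(p)
    crit <- if (branch == "des") rk else rk / 2
    vapply(seq_along(p), function(j) {
      core <- r_i - t_A[j]
      filled <- core <= crit[j]
      cond <- sum(v_i[filled])
      # film in an unfilled cylinder is the exact annulus volume
      film_pore <- sum(v_i[!filled] * (1 - (core[!filled] / r_i[!filled])^2))
      film_ext <- t_A[j] * external_area_m2_g * 1e-4
      (cond + film_pore + film_ext) / silica_constants$gas_to_liquid
    }, numeric(1))
  }

  p_ads <- seq(p_range[1], p_range[2], length.out = n_pressure)
  p_des <- rev(p_ads)
  q_ads <- uptake(p_ads, "ads")
  q_des <- uptake(p_des, "des")
  if (noise_sd > 0) {
    noisy <- with_seed(seed, list(ads = pmax(mult_noise(q_ads, noise_sd), 0),
                                  des = pmax(mult_noise(q_des, noise_sd), 0)))
    q_ads <- noisy$ads
    q_des <- noisy$des
  }
  iso <- sorption_isotherm(c(p_ads, p_des), c(q_ads, q_des),
                           c(rep("ads", n_pressure), rep("des", n_pressure)),
                           hysteresis_tol = max(0.02, 4 * noise_sd))
  attr(iso, "truth") <- list(median_A = median_A, gsd_g = gsd_g,
                             total_volume_cm3_g = total_volume_cm3_g,
                             external_area_m2_g = external_area_m2_g,
                             noise_sd = noise_sd, seed = seed)
  iso
}

#' Generate an isotherm exactly on the BET equation
#'
#' Multilayer BET forward model q = v_m C p / ((1 - p)(1 + (C - 1) p)),
#' the closed-form oracle for the linearized BET regression.
#'
#' @param v_m monolayer capacity, cm3 STP/g
#' @param C BET constant
#' @param p relative pressures (adsorption branch)
#' @return a [sorption_isotherm()] with attribute `truth`
#' @export
gen_bet_isotherm <- function(v_m, C, p = seq(0.01, 0.35, by = 0.01)) {
  q <- v_m * C * p / ((1 - p) * (1 + (C - 1) * p))
  iso <- sorption_isotherm(p, q, rep("ads", length(p)))
  attr(iso, "truth") <- list(v_m = v_m, C = C)
  iso
}

#' Generate an impactor run from a log-normal aerosol
#'
#' The loaded dose is split into device retention, extrathoracic deposition
#' (inlet + pre-separator, split evenly) and impactor-sized mass; the sized
#' mass is partitioned between consecutive effective stage cut-offs by the
#' log-normal cumulative distribution (stage 1 additionally collects
#' everything coarser than its cut-off; the MOC everything finer than
#' stage 7).
#'
#' @param mmad_um true mass median aerodynamic diameter, um
#' @param gsd true geometric standard deviation (> 1)
#' @param total_dose_ug loaded dose, ug
#' @param device_retention_frac fraction of the loaded dose retained in the
#'   device
#' @param extrathoracic_frac fraction of the emitted dose deposited in
#'   inlet + pre-separator
#' @param flow_lpm flow rate, L/min
#' @param table stage table, default [ngi_stage_table]
#' @param noise_sd multiplicative Gaussian noise per location, default 0
#' @param seed RNG seed
#' @return an [impactor_run()] with attribute `truth`
#' @export
gen_impactor_run <- function(mmad_um, gsd, total_dose_ug = 10000,
                             device_retention_frac = 0.1,
                             extrathoracic_frac = 0.1,
                             flow_lpm = 60, table = ngi_stage_table,
                             noise_sd = 0, seed = NULL) {
  stopifnot(gsd > 1, mmad_um > 0, total_dose_ug > 0,
            device_retention_frac >= 0, device_retention_frac < 1,
            extrathoracic_frac >= 0, extrathoracic_frac < 1)
  cuts <- scale_cutoffs(flow_lpm, table)
  device <- device_retention_frac * total_dose_ug
  emitted <- total_dose_ug - device
  extra <- extrathoracic_frac * emitted
  sized <- emitted - extra

  cdf <- stats::pnorm((log(cuts) - log(mmad_um)) / log(gsd))
  # stage k collects mass between cutoff_k and cutoff_(k-1)
  upper <- c(1, cdf[-length(cdf)])
  stage_frac <- upper - cdf
  moc_frac <- cdf[length(cdf)]
  masses <- c(device = unname(device),
              inlet = unname(extra / 2), preseparator = unname(extra / 2),
              stats::setNames(sized * unname(stage_frac), names(cuts)),
              moc = unname(sized * moc_frac))
  if (noise_sd > 0) masses <- with_seed(seed, pmax(mult_noise(masses, noise_sd), 0))
  run <- impactor_run(masses, flow_lpm, total_loaded_dose_ug = total_dose_ug)
  attr(run, "truth") <- list(mmad_um = mmad_um, gsd = gsd,
                             total_dose_ug = total_dose_ug,
                             device_retention_frac = device_retention_frac,
                             extrathoracic_frac = extrathoracic_frac,
                             noise_sd = noise_sd, seed = seed)
  run
}

#' Generate a protein release series with withdrawal/replacement sampling
#'
#' First-order release toward a plateau: the cumulative released mass is
#' plateau x m_loaded x (1 - exp(-rate t)). The vessel is sampled at the
#' scheduled times with exact dilution accounting: each withdrawal removes
#' dissolved protein with the aliquot, and the replacement with fresh medium
#' restores the vessel mass. This is the oracle for the carryover-corrected
#' bookkeeping of [interval_release()].
#'
#' @param plateau_frac fraction of the loaded protein released at infinite
#'   time, in (0, 1]
#' @param rate_h first-order release rate constant, 1/h
#' @param time_h sampling times, h
#' @param withdrawn_g aliquot mass withdrawn (and replaced) at each
#'   sampling, g; recycled to the schedule length
#' @param vessel_mass_g vessel solution mass, g
#' @param omega_lys protein weight fraction of the powder
#' @param sample_mass_mg powder mass, mg
#' @param noise_sd multiplicative Gaussian noise on measured concentrations
#' @param seed RNG seed
#' @return a [release_series()] with attribute `truth`
#' @export
gen_release_series <- function(plateau_frac, rate_h,
                               time_h = c(0.5, 1, 2, 4, 6, 8, 24, 48, 72),
                               withdrawn_g = 2, vessel_mass_g = 5,
                               omega_lys = 0.078, sample_mass_mg = 10,
                               noise_sd = 0, seed = NULL) {
  stopifnot(plateau_frac > 0, plateau_frac <= 1, rate_h >= 0)
  withdrawn_g <- rep_len(withdrawn_g, length(time_h))
  m_loaded <- omega_lys * sample_mass_mg / 1000   # g
  released_cum <- plateau_frac * m_loaded * (1 - exp(-rate_h * time_h))
  dissolved <- 0   # g of protein currently in the vessel
  prev_cum <- 0
  conc <- numeric(length(time_h))
  for (i in seq_along(time_h)) {
    dissolved <- dissolved + (released_cum[i] - prev_cum)
    prev_cum <- released_cum[i]
    conc[i] <- dissolved * 1000 / vessel_mass_g   # mg per g solution
    dissolved <- dissolved * (1 - withdrawn_g[i] / vessel_mass_g)
  }
  if (noise_sd > 0) conc <- with_seed(seed, pmax(mult_noise(conc, noise_sd), 0))
  rs <- release_series(time_h, conc, withdrawn_g, withdrawn_g,
                       vessel_mass_g, omega_lys, sample_mass_mg)
  attr(rs, "truth") <- list(plateau_frac = plateau_frac, rate_h = rate_h,
                            noise_sd = noise_sd, seed = seed)
  rs
}

#' Generate a SAXS curve from the correlation-length model
#'
#' @param porod_scale,porod_exponent,lorentz_scale,lorentz_exponent,xi_A,background
#'   model parameters, see [correlation_length_model()]
#' @param q q grid, nm^-1; default logarithmic over the 0.05-10 nm^-1
#'   experimental range
#' @param noise_sd multiplicative Gaussian noise fraction; also sets the
#'   reported per-point sigma
#' @param seed RNG seed
#' @return a [scattering_curve()] with attribute `truth`
#' @export
gen_scattering <- function(porod_scale, porod_exponent, lorentz_scale,
                           lorentz_exponent, xi_A, background = 0,
                           q = exp(seq(log(0.05), log(10), length.out = 120)),
                           noise_sd = 0, seed = NULL) {
  I0 <- correlation_length_model(q, porod_scale, porod_exponent,
                                 lorentz_scale, lorentz_exponent, xi_A,
                                 background)
  I <- if (noise_sd > 0) with_seed(seed, pmax(mult_noise(I0, noise_sd), 0)) else I0
  sc <- scattering_curve(q, I,
                         sigma = if (noise_sd > 0) pmax(noise_sd * I0, 1e-12),
                         label = "synthetic")
  attr(sc, "truth") <- list(porod_scale = porod_scale,
                            porod_exponent = porod_exponent,
                            lorentz_scale = lorentz_scale,
                            lorentz_exponent = lorentz_exponent,
                            xi_A = xi_A, background = background,
                            noise_sd = noise_sd, seed = seed)
  sc
}

#' Generate a thermogram from a known composition
#'
#' Sum of sigmoidal (logistic) mass-loss steps centered inside each
#' assignment window: water in 25-100, protein plus the silanol
#' condensation loss in 200-800, salts in 800-1000 deg C. Step widths are
#' chosen so the tails at the window boundaries are negligible, which keeps
#' [segment_composition()] round-trips exact to well under 0.1 wt%.
#'
#' @param water_pct,protein_pct,salt_pct target mass losses, wt%
#' @param silanol_pct silanol condensation loss included in the 200-800
#'   window on top of the protein, default 2.2
#' @param n_points number of temperature points from 25 to 1000 deg C
#' @param noise_sd additive Gaussian noise on the residual weight, wt%
#' @param seed RNG seed
#' @return a [thermogram()] with attribute `truth`
#' @export
gen_thermogram <- function(water_pct, protein_pct, salt_pct,
                           silanol_pct = 2.2, n_points = 600,
                           noise_sd = 0, seed = NULL) {
  stopifnot(water_pct >= 0, protein_pct >= 0, salt_pct >= 0,
            water_pct + protein_pct + silanol_pct + salt_pct <= 100)
  temp <- seq(25, 1000, length.out = n_points)
  step <- function(loss, center, width) loss * stats::plogis((temp - center) / width)
  w <- 100 -
    step(water_pct, 62.5, 5) -
    step(protein_pct + silanol_pct, 500, 35) -
    step(salt_pct, 900, 11)
  if (noise_sd > 0)
    w <- with_seed(seed, w + stats::rnorm(length(w), 0, noise_sd))
  tg <- thermogram(temp, w, noise_tol = max(0.2, 6 * noise_sd))
  attr(tg, "truth") <- list(water_pct = water_pct, protein_pct = protein_pct,
                            salt_pct = salt_pct, silanol_pct = silanol_pct,
                            noise_sd = noise_sd, seed = seed)
  tg
}

#' Generate Langmuir adsorption records
#'
#' Loadings lie on the Langmuir curve at the stated equilibrium
#' concentrations (with optional multiplicative noise); initial
#' concentrations are back-computed from the mass balance so the records
#' are self-consistent.
#'
#' @param q_max plateau loading, mg protein per mg sorbent
#' @param K affinity constant, g solution per mg protein
#' @param c_eq equilibrium concentrations, mg per g solution
#' @param solution_mass_g,sorbent_mass_mg batch masses
#' @param noise_sd multiplicative Gaussian noise on loadings
#' @param seed RNG seed
#' @return data frame of records with attribute `truth`
#' @export
gen_adsorption_records <- function(q_max, K,
                                   c_eq = c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2, 3.5, 5),
                                   solution_mass_g = 5, sorbent_mass_mg = 10,
                                   noise_sd = 0, seed = NULL) {
  stopifnot(q_max > 0, K > 0, all(c_eq >= 0))
  loading <- q_max * K * c_eq / (1 + K * c_eq)
  if (noise_sd > 0) loading <- with_seed(seed, pmax(mult_noise(loading, noise_sd), 0))
  c0 <- c_eq + loading * sorbent_mass_mg / solution_mass_g
  rec <- data.frame(c0_mg_g = c0, ceq_mg_g = c_eq,
                    solution_mass_g = solution_mass_g,
                    sorbent_mass_mg = sorbent_mass_mg,
                    loading_mg_mg = loading)
  attr(rec, "truth") <- list(q_max = q_max, K = K, noise_sd = noise_sd,
                             seed = seed)
  rec
}

#' Generate a four-parameter logistic dose-response table
#'
#' @param upper,lower asymptotes (e.g. percent viability)
#' @param inflection inflection concentration
#' @param hill Hill slope
#' @param conc concentration levels; default the 2-fold dilution series
#'   0.0078-1 mg/mL
#' @param noise_sd multiplicative Gaussian noise on responses
#' @param seed RNG seed
#' @return data frame with columns `conc`, `response` and attribute `truth`
#' @export
gen_dose_response <- function(upper = 100, lower = 0, inflection = 0.5,
                              hill = 2,
                              conc = 1 / 2^(7:0), noise_sd = 0, seed = NULL) {
  y <- lower + (upper - lower) / (1 + (conc / inflection)^hill)
  if (noise_sd > 0) y <- with_seed(seed, mult_noise(y, noise_sd))
  dr <- data.frame(conc = conc, response = y)
  attr(dr, "truth") <- list(upper = upper, lower = lower,
                            inflection = inflection, hill = hill,
                            noise_sd = noise_sd, seed = seed)
  dr
}

#' Generate a silica dissolution series
#'
#' First-order dissolution toward complete release of the carrier's Si
#' content: percent dissolved = plateau_pct x (1 - exp(-rate t)), converted
#' to measured Si concentrations through the dose and Si mass fraction.
#'
#' @param plateau_pct asymptotic percent of the theoretical Si dissolved
#' @param rate_h first-order rate constant, 1/h
#' @param time_h sampling times, h
#' @param dose_mg_L particle dose, mg/L
#' @param si_mass_fraction Si mass fraction of the carrier
#' @param noise_sd multiplicative Gaussian noise
#' @param seed RNG seed
#' @return data frame with columns `time_h`, `si_mg_L` and attribute `truth`
#' @export
gen_dissolution_series <- function(plateau_pct = 100, rate_h = 0.12,
                                   time_h = c(1, 2, 4, 6, 8, 24, 48, 72),
                                   dose_mg_L = 30,
                                   si_mass_fraction = 28.08 / 60.08,
                                   noise_sd = 0, seed = NULL) {
  pct <- plateau_pct * (1 - exp(-rate_h * time_h))
  si <- pct / 100 * dose_mg_L * si_mass_fraction
  if (noise_sd > 0) si <- with_seed(seed, pmax(mult_noise(si, noise_sd), 0))
  ds <- data.frame(time_h = time_h, si_mg_L = si)
  attr(ds, "truth") <- list(plateau_pct = plateau_pct, rate_h = rate_h,
                            dose_mg_L = dose_mg_L,
                            si_mass_fraction = si_mass_fraction,
                            noise_sd = noise_sd, seed = seed)
  ds
}
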