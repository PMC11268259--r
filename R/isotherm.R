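#' Construct a nitrogen sorption isotherm
#'
#' Container for a branch-labelled relative-pressure vs quantity-adsorbed
#' curve, the root input for BET surface area, BJH pore-size distribution and
#' total pore volume.
#'
#' @param p_rel relative pressures P/P0, dimensionless in (0, 1)
#' @param q_ads quantity adsorbed, cm3 STP per g
#' @param branch character vector, `"ads"` or `"des"` per point
#' @param temperature_K analysis temperature, default 77.35 K
#' @param adsorbate adsorbate identity, default `"nitrogen"`
#' @param hysteresis_tol tolerance for the physical requirement that at
#'   matching relative pressures the desorption branch lies at or above the
#'   adsorption branch (fraction of the adsorption value)
#' @return object of class `sorption_isotherm`: a data frame with columns
#'   `branch`, `p_rel`, `q_cm3stp_g` and attributes `temperature_K`,
#'   `adsorbate`
#' @export
sorption_isotherm <- function(p_rel, q_ads, branch,
                              temperature_K = 77.35,
                              adsorbate = "nitrogen",
                              hysteresis_tol = 0.02) {
  stopifnot(length(p_rel) == length(q_ads), length(p_rel) == length(branch))
  branch <- match.arg(branch, c("ads", "des"), several.ok = TRUE)
  if (any(p_rel <= 0) || any(p_rel >= 1))
    stop("relative pressures must lie strictly in (0, 1)")
  if (any(q_ads < 0))
    stop("quantity adsorbed must be >= 0 everywhere")

  ads <- p_rel[branch == "ads"]
  des <- p_rel[branch == "des"]
  if (length(ads) > 1 && any(diff(ads) <= 0))
    stop("adsorption-branch pressures must be strictly increasing")
  if (length(des) > 1 && any(diff(des) >= 0))
    stop("desorption-branch pressures must be strictly decreasing")

  iso <- data.frame(branch = branch, p_rel = p_rel, q_cm3stp_g = q_ads,
                    stringsAsFactors = FALSE)

  # hysteresis direction: desorption >= adsorption at matching pressures
  if (length(ads) > 1 && length(des) > 1) {
    shared <- des[des >= min(ads) & des <= max(ads)]
    if (length(shared)) {
      qa <- stats::approx(ads, q_ads[branch == "ads"], xout = shared)$y
      qd <- q_ads[branch == "des"][des %in% shared]
      bad <- qd < qa * (1 - hysteresis_tol)
      if (any(bad, na.rm = TRUE))
        stop("desorption branch falls below adsorption branch beyond tolerance")
    }
  }

  attr(iso, "temperature_K") <- temperature_K
  attr(iso, "adsorbate") <- adsorbate
  class(iso) <- c("sorption_isotherm", "data.frame")
  iso
}

#' @export
print.sorption_isotherm <- function(x, ...) {
  cat(sprintf("Sorption isotherm (%s, %.2f K): %d ads / %d des points, p in [%.3g, %.3g]\n",
              attr(x, "adsorbate"), attr(x, "temperature_K"),
              sum(x$branch == "ads"), sum(x$branch == "des"),
              min(x$p_rel), max(x$p_rel)))
  invisible(x)
}

#' Read a sorption isotherm from CSV
#'
#' Expected header: `branch,p_rel,q_cm3stp_g` with branch in \{ads, des\}.
#'
#' @param path path to a UTF-8 CSV file with dot decimal separator
#' @param ... passed to [sorption_isotherm()]
#' @return a `sorption_isotherm`
#' @export
read_isotherm <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("branch", "p_rel", "q_cm3stp_g")
  if (!all(req %in% names(df)))
    stop("isotherm CSV must have columns: ", paste(req, collapse = ", "))
  sorption_isotherm(df$p_rel, df$q_cm3stp_g, df$branch, ...)
}

branch_points <- function(iso, branch = c("des", "ads")) {
  branch <- match.arg(branch)
  sub <- iso[iso$branch == branch, , drop = FALSE]
  if (nrow(sub) == 0) stop("branch missing: isotherm has no '", branch, "' points")
  sub[order(sub$p_rel), , drop = FALSE]
}
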