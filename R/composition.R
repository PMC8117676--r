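#' Net lipid removal from coverage change
#'
#' The difference in bilayer coverage (equivalently, solvent penetration)
#' before and after incubation, in percent. Negative values indicate net
#' deposition and are reported signed.
#'
#' @param coverage_before,coverage_after material volume fractions in `[0,1]`
#' @param sigma_before,sigma_after optional 1-sigma uncertainties (fractions)
#' @return list with `value` (percent) and `sigma`
#' @export
#' @examples
#' lipid_removal_percent(0.96, 0.90)  # 6 percent
lipid_removal_percent <- function(coverage_before, coverage_after,
                                  sigma_before = 0, sigma_after = 0) {
  stopifnot(coverage_before >= 0, coverage_before <= 1,
            coverage_after >= 0, coverage_after <= 1)
  list(value = 100 * (coverage_before - coverage_after),
       sigma = 100 * sqrt(sigma_before^2 + sigma_after^2))
}

#' Lipid exchange from the dry tail-region SLD
#'
#' The volume fraction of originally deuterated tails replaced by hydrogenous
#' tails, from linear SLD mixing:
#' `100 * (rho_d - rho_obs) / (rho_d - rho_h)`. The observed SLD must be the
#' dry value (solvent contribution removed via the fitted solvent fraction)
#' and must lie between the two endpoints; values outside the interval by
#' more than `tolerance` of its width signal model mis-specification and
#' raise an error.
#'
#' @param fitted_dry_tail_sld observed dry tail SLD, 1e-6 A^-2
#' @param d_lipid_tail_sld,h_lipid_tail_sld deuterated / hydrogenous
#'   endpoint SLDs
#' @param sigma 1-sigma uncertainty on the fitted SLD
#' @param tolerance allowed fractional overshoot of the endpoint interval
#' @return list with `value` (percent) and `sigma`
#' @export
#' @examples
#' exchange_percent(3.97, 6.93, -0.39)  # ~40.4 percent
exchange_percent <- function(fitted_dry_tail_sld, d_lipid_tail_sld,
                             h_lipid_tail_sld, sigma = 0, tolerance = 0.02) {
  if (d_lipid_tail_sld == h_lipid_tail_sld)
    stop("endpoint SLDs must differ")
  lo <- min(d_lipid_tail_sld, h_lipid_tail_sld)
  hi <- max(d_lipid_tail_sld, h_lipid_tail_sld)
  slack <- tolerance * (hi - lo)
  if (fitted_dry_tail_sld < lo - slack || fitted_dry_tail_sld > hi + slack)
    stop("fitted tail SLD ", fitted_dry_tail_sld,
         " outside the endpoint interval [", lo, ", ", hi,
         "]; model mis-specification?")
  denom <- d_lipid_tail_sld - h_lipid_tail_sld
  list(value = 100 * (d_lipid_tail_sld - fitted_dry_tail_sld) / denom,
       sigma = 100 * sigma / abs(denom))
}

#' Protein volume fraction in the membrane core
#'
#' For a lipid-free protein incubation the dry tail region is a two-component
#' mixture of deuterated lipid and protein, so
#' `phi_protein = (rho_d - rho_obs) / (rho_d - rho_protein)`.
#'
#' @param fitted_dry_tail_sld observed dry tail SLD, 1e-6 A^-2
#' @param d_lipid_tail_sld deuterated lipid tail SLD
#' @param protein_sld protein SLD in the relevant contrast
#' @param sigma 1-sigma uncertainty on the fitted SLD
#' @inheritParams exchange_percent
#' @return list with `value` (fraction in `[0,1]`) and `sigma`
#' @export
protein_core_fraction <- function(fitted_dry_tail_sld, d_lipid_tail_sld,
                                  protein_sld, sigma = 0, tolerance = 0.02) {
  if (protein_sld == d_lipid_tail_sld)
    stop("protein and lipid SLDs must differ")
  ex <- exchange_percent(fitted_dry_tail_sld, d_lipid_tail_sld, protein_sld,
                         sigma, tolerance)
  list(value = ex$value / 100, sigma = ex$sigma / 100)
}

#' Fraction of inserted protein co-localised with the membrane core
#'
#' Treats the core and top layers as equal-area slabs, so per-area protein
#' volumes are `phi * t` and
#' `colocalisation = 100 * phi_core t_core / (phi_core t_core + phi_top t_top)`.
#'
#' @param phi_core,phi_top protein volume fractions in `[0,1]`
#' @param core_thickness,top_thickness layer thicknesses, Angstrom (> 0)
#' @return percent
#' @export
#' @examples
#' colocalisation_percent(0.10, 27.2, 0.04, 28)  # ~70.8
colocalisation_percent <- function(phi_core, core_thickness, phi_top,
                                   top_thickness) {
  stopifnot(core_thickness > 0, top_thickness > 0,
            phi_core >= 0, phi_core <= 1, phi_top >= 0, phi_top <= 1)
  num <- phi_core * core_thickness
  den <- num + phi_top * top_thickness
  if (den == 0) stop("both protein amounts are zero; ratio undefined")
  100 * num / den
}

#' Composition report for one before/after membrane pair
#'
#' Bundles the decomposed quantities with first-order propagated
#' uncertainties.
#'
#' @param lipid_removal,lipid_exchange lists from
#'   [lipid_removal_percent()] / [exchange_percent()]
#' @param protein_core,protein_top lists `value`/`sigma` of protein volume
#'   fractions in the core and top layers (optional)
#' @param core_thickness,top_thickness thicknesses used for co-localisation
#' @return a data.frame of class `composition_report` with columns
#'   `quantity`, `value`, `sigma`, `units`
#' @export
composition_report <- function(lipid_removal, lipid_exchange = NULL,
                               protein_core = NULL, protein_top = NULL,
                               core_thickness = NA, top_thickness = NA) {
  rows <- list(c("lipid_removal", lipid_removal$value, lipid_removal$sigma, "%"))
  if (!is.null(lipid_exchange))
    rows <- c(rows, list(c("lipid_exchange", lipid_exchange$value,
                           lipid_exchange$sigma, "%")))
  if (!is.null(protein_core))
    rows <- c(rows, list(c("protein_core_fraction", protein_core$value,
                           protein_core$sigma, "fraction")))
  if (!is.null(protein_top))
    rows <- c(rows, list(c("protein_top_fraction", protein_top$value,
                           protein_top$sigma, "fraction")))
  if (!is.null(protein_core) && !is.null(protein_top) &&
      is.finite(core_thickness) && is.finite(top_thickness)) {
    col <- colocalisation_percent(protein_core$value, core_thickness,
                                  protein_top$value, top_thickness)
    rows <- c(rows, list(c("colocalisation", col, NA, "%")))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(quantity = r[1], value = as.numeric(r[2]),
               sigma = as.numeric(r[3]), units = r[4])))
  class(out) <- c("composition_report", "data.frame")
  out
}

#' Write a composition report as a tab-separated table
#' @param report a [composition_report()]
#' @param path output file
#' @export
write_composition_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Kinetics of lipid replacement from time-sliced single-contrast fits
#'
#' Each slice carries the tail solvent fraction and dry tail SLD fitted
#' against the h-TBS contrast at one timestamp. Three metrics are reported
#' per slice, all relative to the first slice:
#' the change in tail solvent fraction, the exchange (hydrogenous) fraction
#' from the dry SLD, and the combined replaced-lipid fraction
#' `1 - (phi_lipid(t) x_d(t)) / (phi_lipid(0) x_d(0))`, where `x_d` is the
#' deuterated fraction of the remaining lipid.
#'
#' @param slices data.frame with columns `time` (hours, increasing),
#'   `phi_solvent` (tail solvent fraction), `tail_sld_dry` (1e-6 A^-2)
#' @param d_lipid_tail_sld,h_lipid_tail_sld endpoint SLDs of the mixing rule
#' @return data.frame with columns `time`, `delta_phi_solvent`,
#'   `exchange_fraction`, `replaced_fraction`
#' @export
kinetics_series <- function(slices, d_lipid_tail_sld = 6.93,
                            h_lipid_tail_sld = -0.39) {
  req <- c("time", "phi_solvent", "tail_sld_dry")
  if (!all(req %in% names(slices)))
    stop("slices need columns: ", paste(req, collapse = ", "))
  if (any(diff(slices$time) < 0)) stop("timestamps must be non-decreasing")
  xh <- vapply(seq_len(nrow(slices)), function(i)
    exchange_percent(slices$tail_sld_dry[i], d_lipid_tail_sld,
                     h_lipid_tail_sld)$value / 100, numeric(1))
  phi_lipid <- 1 - slices$phi_solvent
  xd <- 1 - xh
  ref <- phi_lipid[1] * xd[1]
  if (ref <= 0) stop("first slice has no deuterated lipid; reference undefined")
  data.frame(time = slices$time,
             delta_phi_solvent = slices$phi_solvent - slices$phi_solvent[1],
             exchange_fraction = xh,
             replaced_fraction = 1 - (phi_lipid * xd) / ref)
}

#' Exponential-approach fit of a kinetics trace
#'
#' Fits `value = plateau * (1 - exp(-time / tau))` by nonlinear least
#' squares, as used to summarise the replaced-lipid trajectories.
#'
#' @param time,value kinetics trace
#' @return list with `plateau`, `tau`, their standard errors and the `nls`
#'   fit object
#' @export
fit_kinetic_plateau <- function(time, value) {
  d <- data.frame(time = time, value = value)
  start <- list(plateau = max(value), tau = max(max(time) / 3, 1e-3))
  fit <- stats::nls(value ~ plateau * (1 - exp(-time / tau)), data = d,
                    start = start)
  s <- summary(fit)$coefficients
  list(plateau = s["plateau", "Estimate"], tau = s["tau", "Estimate"],
       plateau_se = s["plateau", "Std. Error"], tau_se = s["tau", "Std. Error"],
       fit = fit)
}

#' Cholesterol-specificity comparison of exchange on matched membranes
#'
#' Compares the final lipid-exchange percentages measured on h-cholesterol-
#' and d-cholesterol-containing membranes. If cholesterol were exchanged
#' preferentially over the phospholipids, a net difference would appear
#' between the two. The verdict is "no preferential cholesterol exchange"
#' when the difference is below two propagated sigma.
#'
#' @param exchange_h_chol,exchange_d_chol lists with `value` and `sigma`
#'   (percent), e.g. from [exchange_percent()]
#' @return list with `difference`, `sigma`, `significant` (logical at the
#'   2-sigma level) and a `verdict` string
#' @export
#' @examples
#' cholesterol_specificity(list(value = 30.0, sigma = 0.5),
#'                         list(value = 29.1, sigma = 0.5))
cholesterol_specificity <- function(exchange_h_chol, exchange_d_chol) {
  d <- exchange_h_chol$value - exchange_d_chol$value
  s <- sqrt(exchange_h_chol$sigma^2 + exchange_d_chol$sigma^2)
  sig <- is.finite(s) && s > 0 && abs(d) >= 2 * s
  if (s == 0) sig <- abs(d) > 0
  list(difference = d, sigma = s, significant = sig,
       verdict = if (sig) "preferential cholesterol exchange detected"
                 else "no preferential cholesterol exchange")
}

#' Volume-fraction to mole-fraction conversion for exchanged lipid
#'
#' SLDs mix by volume; this helper converts an exchanged volume fraction to
#' a mole fraction using the molecular volumes of the two species.
#'
#' @param volume_fraction exchanged volume fraction in `[0,1]`
#' @param v_incoming,v_original molecular volumes, A^3
#' @return mole fraction
#' @export
exchange_mole_fraction <- function(volume_fraction, v_incoming, v_original) {
  stopifnot(volume_fraction >= 0, volume_fraction <= 1,
            v_incoming > 0, v_original > 0)
  n_in <- volume_fraction / v_incoming
  n_or <- (1 - volume_fraction) / v_original
  n_in / (n_in + n_or)
}
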