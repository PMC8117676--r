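#' Recipe for synthetic multi-contrast reflectivity data
#'
#' Defaults emulate the measurement conditions of a time-of-flight
#' reflectometer in a solid-liquid cell: q from 0.01 to 0.3 A^-1 on a
#' 120-point log grid, constant relative resolution dq/q = 7 percent (fwhm),
#' three solvent contrasts (h-TBS, d-TBS and silicon-matched 38 percent
#' d-TBS), 3 percent relative Gaussian counting noise with a 1e-8 floor.
#'
#' @param truth an [slb_model()] ground truth
#' @param contrasts data.frame with columns `label`, `d2o_fraction`
#' @param q_min,q_max,n_q q grid specification (log-spaced)
#' @param dq_over_q relative resolution fwhm
#' @param noise_rel relative 1-sigma counting noise (0 for exact curves)
#' @param noise_floor absolute noise floor on R
#' @param seed RNG seed; fixed seed gives identical output
#' @return a list of class `nr_recipe`
#' @export
nr_recipe <- function(truth = slb_model(),
                      contrasts = data.frame(
                        label = c("h-TBS", "d-TBS", "cmSi"),
                        d2o_fraction = c(0, 1, 0.38)),
                      q_min = 0.01, q_max = 0.3, n_q = 120,
                      dq_over_q = 0.07, noise_rel = 0.03,
                      noise_floor = 1e-8, seed = 1) {
  stopifnot(noise_rel >= 0, noise_floor >= 0, q_min > 0, q_max > q_min)
  structure(list(truth = truth, contrasts = contrasts, q_min = q_min,
                 q_max = q_max, n_q = n_q, dq_over_q = dq_over_q,
                 noise_rel = noise_rel, noise_floor = noise_floor,
                 seed = seed),
            class = "nr_recipe")
}

log_q_grid <- function(q_min, q_max, n) exp(seq(log(q_min), log(q_max),
                                                length.out = n))

#' Simulate multi-contrast reflectivity curves with known truth
#'
#' For each contrast the exact model curve (Abeles + Gaussian resolution
#' smearing at the recipe's dq/q) is perturbed by Gaussian noise with
#' `dR = max(noise_rel * R, noise_floor)`; the dq column is `dq_over_q * q`.
#' Output is byte-deterministic for a fixed seed, with independent noise
#' realisations across contrasts.
#'
#' @param recipe an [nr_recipe()]
#' @param out_dir optional directory: writes one ASCII curve file per
#'   contrast plus a `truth.json` record
#' @param materials materials table
#' @return list with `datasets` (list of [contrast_dataset()]) and `truth`
#' @export
simulate_reflectivity <- function(recipe, out_dir = NULL,
                                  materials = default_materials()) {
  q <- log_q_grid(recipe$q_min, recipe$q_max, recipe$n_q)
  dq <- recipe$dq_over_q * q
  set.seed(recipe$seed)
  datasets <- lapply(seq_len(nrow(recipe$contrasts)), function(i) {
    lab <- recipe$contrasts$label[i]
    x <- recipe$contrasts$d2o_fraction[i]
    Rm <- slb_model_curve(recipe$truth, q, dq, x, materials)
    dR <- pmax(recipe$noise_rel * Rm, recipe$noise_floor)
    Robs <- if (recipe$noise_rel > 0)
      pmax(Rm + stats::rnorm(length(q), 0, dR), 0) else Rm
    contrast_dataset(nr_curve(q, Robs, dR, dq, label = lab,
                              d2o_fraction = x),
                     d2o_fraction = x, label = lab)
  })
  out <- list(datasets = datasets, truth = recipe$truth, recipe = recipe)
  if (!is.null(out_dir)) write_simulation(out, out_dir, "nr")
  out
}

#' Recipe for synthetic three-contrast SANS data
#'
#' Defaults emulate a pinhole SANS measurement of dilute nanodiscs:
#' q from 0.002 to 0.3 A^-1 on a 150-point log grid, 2 percent relative
#' noise, flat incoherent background interpolated between 0.05 cm^-1 (h-TBS)
#' and 0.005 cm^-1 (d-TBS), contrasts h-TBS / d-TBS / protein-matched
#' 42 percent d-TBS. Wavelength smearing (9 percent fwhm) is off by default.
#'
#' @param truth a [nanodisc_model()]
#' @param contrasts data.frame with `label`, `d2o_fraction`
#' @param q_min,q_max,n_q q grid (log-spaced)
#' @param noise_rel relative 1-sigma noise
#' @param noise_floor absolute noise floor, cm^-1
#' @param background_h,background_d incoherent backgrounds at x = 0 and 1
#' @param smear_fwhm relative wavelength spread (0 = off)
#' @param seed RNG seed
#' @return a list of class `sans_recipe`
#' @export
sans_recipe <- function(truth = nanodisc_model(),
                        contrasts = data.frame(
                          label = c("h-TBS", "d-TBS", "cmP"),
                          d2o_fraction = c(0, 1, 0.42)),
                        q_min = 0.002, q_max = 0.3, n_q = 150,
                        noise_rel = 0.02, noise_floor = 1e-5,
                        background_h = 0.05, background_d = 0.005,
                        smear_fwhm = 0, seed = 1) {
  stopifnot(noise_rel >= 0, q_min > 0, q_max > q_min)
  structure(list(truth = truth, contrasts = contrasts, q_min = q_min,
                 q_max = q_max, n_q = n_q, noise_rel = noise_rel,
                 noise_floor = noise_floor, background_h = background_h,
                 background_d = background_d, smear_fwhm = smear_fwhm,
                 seed = seed),
            class = "sans_recipe")
}

#' Simulate three-contrast SANS curves with known truth
#'
#' @param recipe a [sans_recipe()]
#' @param out_dir optional output directory (curve files + truth record)
#' @param materials materials table
#' @param n_alpha,n_psi orientation quadrature used for the exact curves
#' @return list with `datasets` and `truth`
#' @export
simulate_sans <- function(recipe, out_dir = NULL,
                          materials = default_materials(),
                          n_alpha = 48, n_psi = 24) {
  q <- log_q_grid(recipe$q_min, recipe$q_max, recipe$n_q)
  set.seed(recipe$seed)
  datasets <- lapply(seq_len(nrow(recipe$contrasts)), function(i) {
    lab <- recipe$contrasts$label[i]
    x <- recipe$contrasts$d2o_fraction[i]
    bkg <- recipe$background_h + x * (recipe$background_d -
                                      recipe$background_h)
    Im <- disc_intensity(q, recipe$truth, x, background = bkg,
                         n_alpha = n_alpha, n_psi = n_psi,
                         smear_fwhm = recipe$smear_fwhm,
                         materials = materials)
    dI <- pmax(recipe$noise_rel * Im, recipe$noise_floor)
    Iobs <- if (recipe$noise_rel > 0)
      Im + stats::rnorm(length(q), 0, dI) else Im
    contrast_dataset(sans_curve(q, Iobs, dI, label = lab, d2o_fraction = x),
                     d2o_fraction = x, label = lab, background = bkg)
  })
  out <- list(datasets = datasets, truth = recipe$truth, recipe = recipe)
  if (!is.null(out_dir)) write_simulation(out, out_dir, "sans")
  out
}

#' Simulate a lipid-exchange kinetics run (single contrast)
#'
#' Emulates time-sliced measurements in the h-TBS buffer during incubation:
#' at each slice time the dry tail SLD of the truth model is set to the
#' deuterated/hydrogenous mixture implied by `trajectory(t)` (the exchanged
#' hydrogenous fraction) and a noisy h-TBS curve is generated.
#'
#' @param trajectory function `t -> exchanged fraction in [0, 1]`
#' @param times slice timestamps (hours, increasing)
#' @param recipe an [nr_recipe()]; its contrasts are ignored (h-TBS used)
#' @param d_sld,h_sld tail SLD endpoints, 1e-6 A^-2
#' @param out_dir optional output directory
#' @param materials materials table
#' @return list with `slices` (each: `time`, `dataset`, `truth_exchange`)
#'   and the base `truth`
#' @export
simulate_kinetics <- function(trajectory, times, recipe = nr_recipe(),
                              d_sld = 6.93, h_sld = -0.39, out_dir = NULL,
                              materials = default_materials()) {
  if (any(diff(times) < 0)) stop("slice times must be non-decreasing")
  xh <- vapply(times, trajectory, numeric(1))
  if (any(xh < 0 | xh > 1)) stop("trajectory values must lie in [0, 1]")
  q <- log_q_grid(recipe$q_min, recipe$q_max, recipe$n_q)
  dq <- recipe$dq_over_q * q
  set.seed(recipe$seed)
  slices <- lapply(seq_along(times), function(i) {
    m <- recipe$truth
    m$tail_sld_material <- d_sld + xh[i] * (h_sld - d_sld)
    Rm <- slb_model_curve(m, q, dq, 0, materials)
    dR <- pmax(recipe$noise_rel * Rm, recipe$noise_floor)
    Robs <- if (recipe$noise_rel > 0)
      pmax(Rm + stats::rnorm(length(q), 0, dR), 0) else Rm
    list(time = times[i],
         dataset = contrast_dataset(
           nr_curve(q, Robs, dR, dq, label = "h-TBS", d2o_fraction = 0),
           d2o_fraction = 0, label = "h-TBS"),
         truth_exchange = xh[i])
  })
  out <- list(slices = slices, truth = recipe$truth, recipe = recipe)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(slices))
      write_curve(slices[[i]]$dataset$curve,
                  file.path(out_dir, sprintf("kinetics_t%03d.dat", i)))
    jsonlite::write_json(
      list(times = times, truth_exchange = xh,
           truth = unclass(recipe$truth), seed = recipe$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  out
}

write_simulation <- function(sim, out_dir, kind) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (ds in sim$datasets) {
    fn <- sprintf("%s_%s.dat", kind, gsub("[^A-Za-z0-9]+", "_", ds$label))
    write_curve(ds$curve, file.path(out_dir, fn))
  }
  jsonlite::write_json(list(truth = unclass(sim$truth),
                            seed = sim$recipe$seed, kind = kind),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
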