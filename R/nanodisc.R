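#' Elliptical core-shell bicelle nanodisc model
#'
#' Geometry and materials of a lipoprotein nanodisc: an elliptical lipid
#' bilayer (hydrophobic core of half-height L/2, capped by headgroup face
#' layers) encircled by a protein rim of constant width. The rim height is
#' `L + 2 t_face`; the outer envelope is approximated by an ellipse of
#' semi-axes `(r_minor + d_belt, ellipticity * r_minor + d_belt)`.
#'
#' Region SLDs vary with the solvent through the materials table (labile-H
#' exchange for the protein rim, face hydration for the headgroups).
#'
#' @param r_minor minor semi-axis of the lipid core, Angstrom
#' @param ellipticity axial ratio `r_major / r_minor`, >= 1
#' @param d_belt protein rim (belt) width, Angstrom
#' @param t_face headgroup face-layer thickness, Angstrom
#' @param core_length L, full hydrophobic-core thickness, Angstrom
#' @param core_material,face_material,rim_material material names in the
#'   materials table
#' @param face_hydration solvent volume fraction mixed into the face layers
#' @param scale overall intensity scale (particle volume fraction)
#' @param background flat incoherent background, cm^-1
#' @return an object of class `nanodisc_model`
#' @export
#' @examples
#' nanodisc_model(r_minor = 42, ellipticity = 1.4, d_belt = 11)
nanodisc_model <- function(r_minor = 42.0, ellipticity = 1.4, d_belt = 11.0,
                           t_face = 9.0, core_length = 28,
                           core_material = "hDMPC_tails",
                           face_material = "pc_head",
                           rim_material = "protein",
                           face_hydration = 0.3,
                           scale = 1e-3, background = 0) {
  if (r_minor <= 0 || d_belt <= 0 || t_face <= 0 || core_length <= 0)
    stop("all nanodisc lengths must be positive")
  if (ellipticity < 1) stop("ellipticity must be >= 1")
  if (face_hydration < 0 || face_hydration > 1)
    stop("face_hydration must lie in [0, 1]")
  structure(list(r_minor = r_minor, ellipticity = ellipticity,
                 d_belt = d_belt, t_face = t_face, core_length = core_length,
                 core_material = core_material, face_material = face_material,
                 rim_material = rim_material, face_hydration = face_hydration,
                 scale = scale, background = background),
            class = "nanodisc_model")
}

#' Per-region nanodisc SLDs in a given solvent contrast
#'
#' @param model a [nanodisc_model()]
#' @param d2o_fraction buffer D2O fraction
#' @param materials materials table
#' @return list with `core`, `face`, `rim`, `solvent` SLDs (1e-6 A^-2)
#' @export
disc_slds <- function(model, d2o_fraction, materials = default_materials()) {
  s <- solvent_sld(d2o_fraction, materials)
  face_dry <- material_sld(model$face_material, d2o_fraction, materials)
  list(core = material_sld(model$core_material, d2o_fraction, materials),
       face = (1 - model$face_hydration) * face_dry + model$face_hydration * s,
       rim = material_sld(model$rim_material, d2o_fraction, materials),
       solvent = s)
}

# The three coaxial elliptical cylinders whose superposition represents the
# disc: outer envelope (rim contrast), face correction, core correction.
disc_regions <- function(model) {
  r <- model$r_minor; e <- model$ellipticity
  d <- model$d_belt; tf <- model$t_face; hL <- model$core_length / 2
  list(
    outer = list(a = r + d, b = e * r + d, h = hL + tf),
    face  = list(a = r,     b = e * r,     h = hL + tf),
    core  = list(a = r,     b = e * r,     h = hL))
}

sinc1 <- function(x) ifelse(abs(x) < 1e-6, 1 - x^2 / 6, sin(x) / x)
j1c <- function(x) {
  out <- ifelse(abs(x) < 1e-6, 1 - x^2 / 8, NA_real_)
  big <- is.na(out)
  out[big] <- 2 * besselJ(x[big], 1) / x[big]
  out
}

# Single elliptical cylinder amplitude / volume:
#   sinc(q h cos(alpha)) * 2 J1(u) / u,  u = q r(psi) sin(alpha),
#   r(psi) = sqrt(a^2 cos^2 psi + b^2 sin^2 psi)
ell_cyl_amp <- function(q, alpha, psi, a, b, h) {
  rp <- sqrt(a^2 * cos(psi)^2 + b^2 * sin(psi)^2)
  u <- q * rp * sin(alpha)
  sinc1(q * h * cos(alpha)) * j1c(u)
}

#' Scattering amplitude of the nanodisc at one orientation
#'
#' Superposition of the three coaxial elliptical cylinders, each weighted by
#' its volume and SLD contrast step: the outer envelope carries
#' `rho_rim - rho_solvent`, the face cylinder corrects to
#' `rho_face - rho_rim`, and the core cylinder to `rho_core - rho_face`.
#'
#' @param q momentum transfer, A^-1 (vectorised)
#' @param alpha angle between q and the disc axis, `[0, pi/2]`
#' @param psi in-plane azimuth of q, `[0, pi/2]`
#' @param model a [nanodisc_model()]
#' @param d2o_fraction buffer D2O fraction
#' @param materials materials table
#' @return complex-free real amplitude in units of (1e-6 A^-2) * A^3
#' @export
disc_amplitude <- function(q, alpha, psi, model, d2o_fraction,
                           materials = default_materials()) {
  stopifnot(alpha >= 0, alpha <= pi / 2 + 1e-12,
            psi >= 0, psi <= pi / 2 + 1e-12)
  sl <- disc_slds(model, d2o_fraction, materials)
  rg <- disc_regions(model)
  drho <- c(sl$rim - sl$solvent, sl$face - sl$rim, sl$core - sl$face)
  amp <- 0
  for (i in seq_along(rg)) {
    g <- rg[[i]]
    V <- pi * g$a * g$b * 2 * g$h
    amp <- amp + drho[i] * V * ell_cyl_amp(q, alpha, psi, g$a, g$b, g$h)
  }
  amp
}

#' Forward scattering length of the nanodisc
#'
#' `sum over regions of drho * V`, the q -> 0 limit of the amplitude.
#'
#' @inheritParams disc_amplitude
#' @return excess scattering length in (1e-6 A^-2) * A^3
#' @export
disc_forward_amplitude <- function(model, d2o_fraction,
                                   materials = default_materials()) {
  disc_amplitude(0, 0, 0, model, d2o_fraction, materials)
}

# Orientation-averaged |F|^2 on a q grid. Geometry-only decomposition:
# returns per-region amplitude matrices so contrasts reweight cheaply.
disc_geometry_terms <- function(q, model, n_alpha = 48, n_psi = 24) {
  if (n_alpha < 8 || n_psi < 8)
    stop("orientation quadrature order must be >= 8")
  ga <- pracma::gaussLegendre(n_alpha, 0, pi / 2)
  gp <- pracma::gaussLegendre(n_psi, 0, pi / 2)
  # weights: sin(alpha) d(alpha) (normalised to 1) x uniform psi
  wa <- ga$w * sin(ga$x); wa <- wa / sum(wa)
  wp <- gp$w / sum(gp$w)
  alpha <- rep(ga$x, times = n_psi)
  psi <- rep(gp$x, each = n_alpha)
  w <- as.vector(outer(wa, wp))
  rg <- disc_regions(model)
  sa <- sin(alpha); ca <- cos(alpha)
  G <- lapply(rg, function(g) {
    V <- pi * g$a * g$b * 2 * g$h
    rp <- sqrt(g$a^2 * cos(psi)^2 + g$b^2 * sin(psi)^2)
    u <- outer(q, rp * sa)                     # nq x nor
    zc <- outer(q, ca * g$h)
    V * sinc1(zc) * j1c(u)
  })
  Vo <- with(disc_regions(model)$outer, pi * a * b * 2 * h)
  list(G = G, w = w, V_outer = Vo)
}

#' Orientation-averaged SANS intensity of the nanodisc
#'
#' `I(q) = scale / V_outer * <|F|^2> + background`, with the orientational
#' average taken over the disc axis (weight `sin(alpha)`) and the in-plane
#' azimuth (uniform), both by fixed-order Gauss-Legendre quadrature on
#' `[0, pi/2]`. Quadrature orders below 8 are refused. Optional Gaussian
#' wavelength smearing (relative fwhm) re-evaluates the model at shifted q.
#'
#' @param q momentum-transfer grid, A^-1
#' @param model a [nanodisc_model()]
#' @param d2o_fraction buffer D2O fraction
#' @param scale,background override the model's nuisance parameters
#' @param n_alpha,n_psi orientation quadrature orders (>= 8)
#' @param smear_fwhm relative Gaussian wavelength spread (e.g. 0.09); 0
#'   disables smearing
#' @param materials materials table
#' @return intensity in cm^-1
#' @export
disc_intensity <- function(q, model, d2o_fraction,
                           scale = model$scale, background = model$background,
                           n_alpha = 48, n_psi = 24, smear_fwhm = 0,
                           materials = default_materials()) {
  if (smear_fwhm > 0) {
    return(smear_gaussian(q, dq = smear_fwhm * q, model = function(qq)
      disc_intensity(qq, model, d2o_fraction, scale, background,
                     n_alpha, n_psi, smear_fwhm = 0, materials = materials)))
  }
  gt <- disc_geometry_terms(q, model, n_alpha, n_psi)
  sl <- disc_slds(model, d2o_fraction, materials)
  drho <- c(sl$rim - sl$solvent, sl$face - sl$rim, sl$core - sl$face) * 1e-6
  F <- drho[1] * gt$G[[1]] + drho[2] * gt$G[[2]] + drho[3] * gt$G[[3]]
  mean_F2 <- as.vector(F^2 %*% gt$w)
  1e8 * scale * mean_F2 / gt$V_outer + background
}

#' Simultaneous three-contrast SANS fit of the nanodisc model
#'
#' Shape parameters (`r_minor`, `ellipticity`, `d_belt`, `t_face`,
#' `core_length`, `face_hydration`) are shared across contrasts; per-contrast
#' SLDs follow from the materials table and the labile-hydrogen rule.
#' Per-contrast nuisances can be freed as `"scale:<label>"` /
#' `"background:<label>"`. Optimiser contract as in [fit_global()]:
#' seeded differential evolution followed by a local polish.
#'
#' @param datasets list of [contrast_dataset()]s holding [sans_curve()]s
#' @param model_template a [nanodisc_model()]
#' @param free character vector of free parameter names (may be empty)
#' @param bounds named list or 2-column matrix of box constraints
#' @param seed RNG seed
#' @param materials materials table
#' @param n_alpha,n_psi orientation quadrature orders used during fitting
#' @param smear_fwhm relative wavelength smearing applied to the model
#' @param control optimiser overrides (`np`, `maxiter`, `tol`, `patience`)
#' @return a `scatter_fit` (see [fit_global()])
#' @export
fit_sans_global <- function(datasets, model_template, free, bounds = NULL,
                            seed = 1, materials = default_materials(),
                            n_alpha = 32, n_psi = 16, smear_fwhm = 0,
                            control = list()) {
  if (inherits(datasets, "contrast_dataset")) datasets <- list(datasets)
  npts <- sum(vapply(datasets, function(d) nrow(d$curve), integer(1)))

  chi2_fun <- function(model, dsets) {
    gt <- NULL; gt_q <- NULL           # cache geometry terms per shared q grid
    sum(vapply(dsets, function(ds) {
      cv <- ds$curve
      if (any(cv$dI <= 0)) stop("dataset '", ds$label,
                                "' has non-positive dI; weights undefined")
      if (is.null(gt) || !identical(gt_q, cv$q)) {
        gt <<- disc_geometry_terms(cv$q, model, n_alpha, n_psi)
        gt_q <<- cv$q
      }
      sl <- disc_slds(model, ds$d2o_fraction, materials)
      drho <- c(sl$rim - sl$solvent, sl$face - sl$rim, sl$core - sl$face) * 1e-6
      F <- drho[1] * gt$G[[1]] + drho[2] * gt$G[[2]] + drho[3] * gt$G[[3]]
      Im <- 1e8 * ds$scale * model$scale * as.vector(F^2 %*% gt$w) /
        gt$V_outer + ds$background
      if (smear_fwhm > 0)
        Im <- smear_gaussian(cv$q, R = Im, dq = smear_fwhm * cv$q)
      sum(((Im - cv$I) / cv$dI)^2)
    }, numeric(1)))
  }

  if (length(free) == 0) {
    chi2 <- chi2_fun(model_template, datasets)
    return(structure(list(parameters = stats::setNames(numeric(0), character(0)),
                          model = model_template, datasets = datasets,
                          chi_square = chi2, dof = npts, converged = TRUE,
                          seed = seed, free = character(0), bounds = NULL,
                          sigma = NULL, resamples = NULL, kind = "sans",
                          materials = materials),
                     class = "scatter_fit"))
  }

  b <- as_bounds_matrix(bounds, free)
  objective_for <- function(dsets) {
    function(par) {
      ap <- apply_free_parameters(par, free, model_template, dsets)
      chi2_fun(ap$model, ap$datasets)
    }
  }
  obj <- objective_for(datasets)
  set.seed(seed)
  de <- de_optim(obj, b[, 1], b[, 2],
                 np = control$np %||% NULL,
                 maxiter = control$maxiter %||% 120,
                 tol = control$tol %||% 1e-8,
                 patience = control$patience %||% 15)
  pol <- stats::nlminb(de$par, obj, lower = b[, 1], upper = b[, 2])
  par <- if (pol$objective <= de$value) pol$par else de$par
  names(par) <- free
  ap <- apply_free_parameters(par, free, model_template, datasets)
  chi2 <- chi2_fun(ap$model, ap$datasets)
  dof <- npts - length(free)
  if (dof <= 0) stop("degrees of freedom must be positive")
  structure(list(parameters = par, model = ap$model, datasets = ap$datasets,
                 chi_square = chi2, dof = dof,
                 converged = de$converged || pol$convergence == 0,
                 seed = seed, free = free, bounds = b, sigma = NULL,
                 resamples = NULL, kind = "sans", materials = materials,
                 objective_for = objective_for),
            class = "scatter_fit")
}
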