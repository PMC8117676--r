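#' Joint chi-square of an SLB model against multiple contrasts
#'
#' `chi2 = sum over datasets and points of
#' ((scale * R_model + background - R_obs) / dR)^2`, where the model curve is
#' computed with the Abeles formalism, solvent-mixed for each dataset's
#' D2O fraction, and smeared per point with its resolution column.
#'
#' @param model an [slb_model()]
#' @param datasets list of [contrast_dataset()] objects holding [nr_curve()]s
#' @param materials materials table
#' @param n_smear resolution quadrature order
#' @return chi-square (not reduced)
#' @export
joint_chi_square <- function(model, datasets, materials = default_materials(),
                             n_smear = 17) {
  if (!length(datasets)) stop("need at least one dataset")
  if (inherits(datasets, "contrast_dataset")) datasets <- list(datasets)
  sum(vapply(datasets, function(ds) {
    cv <- ds$curve
    if (any(cv$dR <= 0)) stop("dataset '", ds$label,
                              "' has non-positive dR; weights undefined")
    Rm <- slb_model_curve(model, cv$q, cv$dq, ds$d2o_fraction, materials,
                          n_smear)
    sum(((ds$scale * Rm + ds$background - cv$R) / cv$dR)^2)
  }, numeric(1)))
}

# Smeared model reflectivity for one contrast
slb_model_curve <- function(model, q, dq, d2o_fraction,
                            materials = default_materials(), n_smear = 17) {
  ssld <- solvent_sld(d2o_fraction, materials)
  stack <- build_slb_stack(model, ssld, d2o_fraction, materials)
  if (all(dq == 0)) return(reflectivity_abeles(stack, q))
  smear_gaussian(q, dq = dq, model = function(qq)
    reflectivity_abeles(stack, qq), n = n_smear)
}

#' Mean molecular area of one bilayer layer
#'
#' `MMA = V / (t_leaflet * coverage)`: the in-plane area per molecule implied
#' by a layer's per-leaflet thickness, coverage and molecular volume. For the
#' tail region pass half the full hydrophobic-core thickness.
#'
#' @param thickness_per_leaflet Angstrom, > 0
#' @param coverage material volume fraction, in (0, 1]
#' @param molecular_volume Angstrom^3
#' @return area in Angstrom^2
#' @export
#' @examples
#' layer_mma(27.2 / 2, 0.96, 782)  # DMPC tails: ~59.9
#' layer_mma(9.0, 0.62, 319)       # PC heads:  ~57.2
layer_mma <- function(thickness_per_leaflet, coverage, molecular_volume) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (thickness_per_leaflet <= 0) stop("thickness must be > 0")
  molecular_volume / (thickness_per_leaflet * coverage)
}

# Relative head/tail MMA mismatch of an SLB model
slb_mma_mismatch <- function(model, head_volume = 319, tail_volume = 782) {
  mh <- layer_mma(model$head_thickness, model$head_coverage, head_volume)
  mt <- layer_mma(model$tail_thickness / 2, model$tail_coverage, tail_volume)
  abs(mh - mt) / ((mh + mt) / 2)
}

# Apply a named free-parameter vector to a model template and dataset
# nuisances. Names are model fields, or "scale:<label>" / "background:<label>".
apply_free_parameters <- function(par, free, model, datasets) {
  for (i in seq_along(free)) {
    nm <- free[i]
    if (grepl("^(scale|background):", nm)) {
      kind <- sub(":.*$", "", nm)
      lab <- sub("^[a-z]+:", "", nm)
      hit <- FALSE
      for (j in seq_along(datasets)) {
        if (identical(datasets[[j]]$label, lab)) {
          datasets[[j]][[kind]] <- par[i]
          hit <- TRUE
        }
      }
      if (!hit) stop("no dataset labelled '", lab, "' for free parameter ", nm)
    } else {
      if (is.null(model[[nm]])) stop("unknown free parameter: ", nm)
      model[[nm]] <- par[i]
    }
  }
  list(model = model, datasets = datasets)
}

as_bounds_matrix <- function(bounds, free) {
  if (is.list(bounds)) {
    b <- t(vapply(free, function(nm) {
      if (is.null(bounds[[nm]])) stop("no bounds for free parameter ", nm)
      as.numeric(bounds[[nm]])
    }, numeric(2)))
  } else {
    b <- as.matrix(bounds)
    if (is.null(rownames(b))) rownames(b) <- free
    b <- b[free, , drop = FALSE]
  }
  if (!all(is.finite(b))) stop("bounds must be finite")
  colnames(b) <- c("lower", "upper")
  b
}

#' Simultaneous fit of one model to several contrasts
#'
#' Population-based global optimisation (differential evolution, seeded and
#' deterministic) followed by a local polish with [stats::nlminb()]. All
#' structural parameters are shared across contrasts; per-contrast nuisance
#' parameters can be freed by naming them `"scale:<label>"` or
#' `"background:<label>"`. The head/tail mean-molecular-area consistency
#' constraint is applied as a soft penalty when the two areas differ by more
#' than `mma_tolerance`.
#'
#' @param datasets list of [contrast_dataset()]s
#' @param model_template an [slb_model()] supplying all fixed parameters and
#'   starting values
#' @param free character vector of free parameter names (may be empty)
#' @param bounds named list `name -> c(lower, upper)` or a 2-column matrix
#'   with rownames; required when `free` is non-empty
#' @param seed integer RNG seed; two runs with the same seed give identical
#'   results
#' @param materials materials table
#' @param mma_weight penalty weight for the MMA constraint (0 disables)
#' @param mma_tolerance allowed relative head/tail MMA mismatch
#' @param head_volume,tail_volume molecular volumes used by the constraint
#' @param control list overriding optimiser settings: `np`, `maxiter`, `tol`,
#'   `patience`, `n_smear`
#' @return an object of class `scatter_fit`: named best-fit `parameters`, the
#'   updated `model` and `datasets`, `chi_square`, `dof`, `converged`, `seed`,
#'   and (after [mc_uncertainty()]) per-parameter `sigma` and a `resamples`
#'   table
#' @export
fit_global <- function(datasets, model_template, free, bounds = NULL,
                       seed = 1, materials = default_materials(),
                       mma_weight = 1e3, mma_tolerance = 0.05,
                       head_volume = 319, tail_volume = 782,
                       control = list()) {
  if (inherits(datasets, "contrast_dataset")) datasets <- list(datasets)
  npts <- sum(vapply(datasets, function(d) nrow(d$curve), integer(1)))
  n_smear <- control$n_smear %||% 17

  penalised <- function(model, dsets) {
    chi2 <- joint_chi_square(model, dsets, materials, n_smear)
    if (mma_weight > 0) {
      mism <- slb_mma_mismatch(model, head_volume, tail_volume)
      chi2 <- chi2 + mma_weight * max(0, mism - mma_tolerance)^2 * npts
    }
    chi2
  }

  if (length(free) == 0) {
    chi2 <- joint_chi_square(model_template, datasets, materials, n_smear)
    return(structure(list(parameters = stats::setNames(numeric(0), character(0)),
                          model = model_template, datasets = datasets,
                          chi_square = chi2, dof = npts, converged = TRUE,
                          seed = seed, free = character(0), bounds = NULL,
                          sigma = NULL, resamples = NULL,
                          kind = "nr", materials = materials,
                          n_smear = n_smear),
                     class = "scatter_fit"))
  }

  b <- as_bounds_matrix(bounds, free)
  objective_for <- function(dsets) {
    function(par) {
      ap <- apply_free_parameters(par, free, model_template, dsets)
      penalised(ap$model, ap$datasets)
    }
  }
  obj <- objective_for(datasets)

  set.seed(seed)
  de <- de_optim(obj, b[, 1], b[, 2],
                 np = control$np %||% NULL,
                 maxiter = control$maxiter %||% 150,
                 tol = control$tol %||% 1e-8,
                 patience = control$patience %||% 20)
  pol <- stats::nlminb(de$par, obj, lower = b[, 1], upper = b[, 2])
  par <- if (pol$objective <= de$value) pol$par else de$par
  names(par) <- free
  ap <- apply_free_parameters(par, free, model_template, datasets)
  chi2 <- joint_chi_square(ap$model, ap$datasets, materials, n_smear)
  dof <- npts - length(free)
  if (dof <= 0) stop("degrees of freedom must be positive")
  structure(list(parameters = par, model = ap$model, datasets = ap$datasets,
                 chi_square = chi2, dof = dof,
                 converged = de$converged || pol$convergence == 0,
                 seed = seed, free = free, bounds = b,
                 sigma = NULL, resamples = NULL,
                 kind = "nr", materials = materials, n_smear = n_smear,
                 objective_for = objective_for),
            class = "scatter_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scatter_fit <- function(x, ...) {
  cat("Simultaneous", x$kind, "fit:", length(x$datasets), "contrast(s),",
      "chi2 =", format(x$chi_square, digits = 5), "on", x$dof, "dof\n")
  if (length(x$parameters)) {
    tab <- data.frame(value = x$parameters)
    if (!is.null(x$sigma)) tab$sigma <- x$sigma
    print(tab)
  }
  invisible(x)
}

#' Monte-Carlo uncertainty of a fit
#'
#' Each resample perturbs every observed point by a Gaussian of its quoted
#' 1-sigma uncertainty and refits starting from the best-fit parameters
#' (local polish). The parameter uncertainty is the standard deviation over
#' resamples. When every uncertainty is zero the perturbations vanish and
#' all sigmas are 0 without refitting.
#'
#' @param fit a `scatter_fit` from [fit_global()] or [fit_sans_global()]
#' @param datasets the datasets that were fitted
#' @param n_resamples number of resamples (>= 2)
#' @param seed RNG seed
#' @return the fit with `sigma` (named vector) and `resamples` (matrix with
#'   one row per resample) filled in
#' @export
mc_uncertainty <- function(fit, datasets, n_resamples = 100, seed = 1) {
  stopifnot(n_resamples >= 2)
  if (inherits(datasets, "contrast_dataset")) datasets <- list(datasets)
  free <- fit$free
  if (!length(free)) {
    fit$sigma <- stats::setNames(numeric(0), character(0))
    return(fit)
  }
  ycol <- if (fit$kind == "sans") "I" else "R"
  dcol <- if (fit$kind == "sans") "dI" else "dR"
  alldR <- unlist(lapply(datasets, function(d) d$curve[[dcol]]))
  if (all(alldR == 0)) {
    fit$sigma <- stats::setNames(rep(0, length(free)), free)
    fit$resamples <- matrix(rep(fit$parameters, each = n_resamples),
                            n_resamples, dimnames = list(NULL, free))
    return(fit)
  }
  set.seed(seed)
  res <- matrix(NA_real_, n_resamples, length(free),
                dimnames = list(NULL, free))
  for (r in seq_len(n_resamples)) {
    pert <- lapply(datasets, function(d) {
      d$curve[[ycol]] <- d$curve[[ycol]] +
        stats::rnorm(nrow(d$curve), 0, d$curve[[dcol]])
      d
    })
    obj <- fit$objective_for(pert)
    pol <- stats::nlminb(fit$parameters, obj,
                         lower = fit$bounds[, 1], upper = fit$bounds[, 2],
                         control = list(rel.tol = 1e-8, eval.max = 250,
                                        iter.max = 60))
    res[r, ] <- pol$par
  }
  fit$sigma <- apply(res, 2, stats::sd)
  fit$resamples <- res
  fit
}

#' F-test comparison of nested fits
#'
#' `F = ((chi2_r - chi2_f) / (dof_r - dof_f)) / (chi2_f / dof_f)` with the
#' p-value from the upper tail of the F distribution, assuming normally
#' distributed errors. The restricted model must be nested in the full one
#' (fewer free parameters, hence more degrees of freedom).
#'
#' @param fit_restricted,fit_full `scatter_fit` objects or lists with
#'   elements `chi_square` and `dof`
#' @return list with `F`, `df1`, `df2`, `p_value`
#' @export
f_test_model_comparison <- function(fit_restricted, fit_full) {
  cr <- fit_restricted$chi_square; dr <- fit_restricted$dof
  cf <- fit_full$chi_square;       df_ <- fit_full$dof
  if (is.null(cr) || is.null(cf)) stop("fits must carry chi_square and dof")
  if (cf <= 0) stop("full-model chi-square must be positive")
  if (dr <= df_) stop("models not nested: restricted dof must exceed full dof")
  Fval <- ((cr - cf) / (dr - df_)) / (cf / df_)
  p <- stats::pf(Fval, dr - df_, df_, lower.tail = FALSE)
  list(F = Fval, df1 = dr - df_, df2 = df_, p_value = p)
}

#' Fit time-sliced single-contrast kinetics data
#'
#' Codifies the kinetics protocol: every structural parameter is fixed at
#' its pre-incubation value and only the tail SLD, tail coverage (solvation)
#' and, when a top layer is present, its coverage are freed for each slice —
#' single-contrast data cannot constrain more. Returns the slice table
#' consumed by [kinetics_series()].
#'
#' @param slices list of slices from [simulate_kinetics()] (each with
#'   `time` and `dataset`) or equivalent
#' @param model0 pre-incubation [slb_model()] used as template and start
#' @param bounds named bounds list; defaults cover the freed parameters
#' @param seed RNG seed
#' @param materials materials table
#' @param control optimiser overrides
#' @return data.frame with `time`, `phi_solvent`, `tail_sld_dry`
#' @export
fit_kinetics_slices <- function(slices, model0, bounds = NULL, seed = 1,
                                materials = default_materials(),
                                control = list(maxiter = 60, patience = 10)) {
  if (is.null(bounds)) {
    bounds <- list(tail_sld_material = c(-0.6, 7),
                   tail_coverage = c(0.4, 1))
    if (model0$top_layer_thickness > 0)
      bounds$top_layer_coverage <- c(0, 0.3)
  }
  free <- names(bounds)
  rows <- lapply(seq_along(slices), function(i) {
    sl <- slices[[i]]
    fit <- fit_global(list(sl$dataset), model0, free = free, bounds = bounds,
                      seed = seed + i, materials = materials,
                      control = control)
    data.frame(time = sl$time,
               phi_solvent = 1 - fit$model$tail_coverage,
               tail_sld_dry = fit$model$tail_sld_material)
  })
  do.call(rbind, rows)
}
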