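test_that("joint chi-square vanishes at truth and increases under perturbation", {
  truth <- ddmpc_model()
  sim <- simulate_reflectivity(nr_recipe(truth = truth, noise_rel = 0,
                                         n_q = 60, seed = 1))
  expect_lt(joint_chi_square(truth, sim$datasets), 1e-6)

  # perturbing the tail SLD strictly increases chi2 on h-TBS data alone
  h <- sim$datasets[1]
  pert <- truth
  pert$tail_sld_material <- truth$tail_sld_material + 1
  expect_gt(joint_chi_square(pert, h), joint_chi_square(truth, h))

  # zero uncertainties are rejected
  bad <- sim$datasets[[1]]
  bad$curve$dR <- 0
  expect_error(joint_chi_square(truth, list(bad)), "dR")
})

test_that("chi2/dof of noisy data at truth is consistent with counting statistics", {
  truth <- ddmpc_model()
  red <- vapply(1:8, function(s) {
    sim <- simulate_reflectivity(nr_recipe(truth = truth, n_q = 60, seed = s))
    npts <- sum(vapply(sim$datasets, function(d) nrow(d$curve), integer(1)))
    joint_chi_square(truth, sim$datasets) / npts
  }, numeric(1))
  # each reduced chi2 ~ 1 +/- 3/sqrt(dof); the mean is much tighter
  expect_true(all(abs(red - 1) < 3 / sqrt(180) + 0.05))
  expect_lt(abs(mean(red) - 1), 0.05)
})

test_that("global co-refinement recovers structure from noiseless data and is deterministic", {
  truth <- ddmpc_model()
  sim <- simulate_reflectivity(nr_recipe(truth = truth, noise_rel = 0,
                                         n_q = 60, seed = 1))
  start <- ddmpc_model(head_thickness = 11, tail_thickness = 24)
  bounds <- list(head_thickness = c(6, 14), tail_thickness = c(20, 34))
  fit <- fit_global(sim$datasets, start,
                    free = c("head_thickness", "tail_thickness"),
                    bounds = bounds, seed = 3,
                    control = list(maxiter = 80, patience = 12))
  expect_lt(abs(fit$parameters[["head_thickness"]] - 9.0) / 9.0, 0.01)
  expect_lt(abs(fit$parameters[["tail_thickness"]] - 27.2) / 27.2, 0.01)

  # empty free set returns the template chi-square unchanged
  f0 <- fit_global(sim$datasets, truth, free = character(0))
  expect_identical(f0$model, truth)
  expect_equal(f0$chi_square, joint_chi_square(truth, sim$datasets))

  # determinism: same seed, bit-identical parameters
  small <- sim$datasets[1]
  ctrl <- list(maxiter = 8, patience = 3)
  b1 <- fit_global(small, start, free = "tail_thickness",
                   bounds = bounds["tail_thickness"], seed = 11,
                   control = ctrl)
  b2 <- fit_global(small, start, free = "tail_thickness",
                   bounds = bounds["tail_thickness"], seed = 11,
                   control = ctrl)
  expect_identical(b1$parameters, b2$parameters)
})

test_that("Monte-Carlo uncertainties behave like resampling errors", {
  truth <- ddmpc_model()
  sim <- simulate_reflectivity(fast_nr_recipe(truth, seed = 2))
  bounds <- list(tail_sld_material = c(3, 7.5))
  fit <- fit_global(sim$datasets, truth, free = "tail_sld_material",
                    bounds = bounds, seed = 4,
                    control = list(maxiter = 40, patience = 8))
  fit <- mc_uncertainty(fit, sim$datasets, n_resamples = 15, seed = 5)
  expect_true(all(fit$sigma >= 0))
  expect_equal(dim(fit$resamples), c(15L, 1L))

  # noiseless data: zero quoted uncertainties give zero parameter sigma
  # without any refitting
  sim0 <- simulate_reflectivity(nr_recipe(truth = truth, noise_rel = 0,
                                          noise_floor = 0, n_q = 40, seed = 1))
  f0 <- structure(list(parameters = c(tail_sld_material = 6.93),
                       free = "tail_sld_material", kind = "nr"),
                  class = "scatter_fit")
  s0 <- mc_uncertainty(f0, sim0$datasets, n_resamples = 5, seed = 1)
  expect_equal(unname(s0$sigma), 0)

  # doubling all dR inflates the parameter uncertainty
  sim2 <- sim
  sim2$datasets <- lapply(sim$datasets, function(d) {
    d$curve$dR <- 2 * d$curve$dR; d
  })
  fit2 <- fit_global(sim2$datasets, truth, free = "tail_sld_material",
                     bounds = bounds, seed = 4,
                     control = list(maxiter = 40, patience = 8))
  fit2 <- mc_uncertainty(fit2, sim2$datasets, n_resamples = 15, seed = 5)
  expect_gt(fit2$sigma[["tail_sld_material"]],
            fit$sigma[["tail_sld_material"]])
})

test_that("three-contrast co-refinement constrains the tail SLD better than one contrast", {
  truth <- ddmpc_model()
  sim <- simulate_reflectivity(fast_nr_recipe(truth, seed = 9))
  bounds <- list(tail_sld_material = c(3, 7.5))
  ctrl <- list(maxiter = 40, patience = 8)
  f3 <- mc_uncertainty(
    fit_global(sim$datasets, truth, free = "tail_sld_material",
               bounds = bounds, seed = 1, control = ctrl),
    sim$datasets, n_resamples = 15, seed = 2)
  f1 <- mc_uncertainty(
    fit_global(sim$datasets[1], truth, free = "tail_sld_material",
               bounds = bounds, seed = 1, control = ctrl),
    sim$datasets[1], n_resamples = 15, seed = 2)
  expect_lt(f3$sigma[["tail_sld_material"]], f1$sigma[["tail_sld_material"]])
})

test_that("F-test matches the F-distribution and rejects non-nested input", {
  same <- list(chi_square = 100, dof = 100)
  expect_equal(f_test_model_comparison(list(chi_square = 100, dof = 101),
                                       same)$F, 0)
  expect_equal(f_test_model_comparison(list(chi_square = 100, dof = 101),
                                       same)$p_value, 1)

  ft <- f_test_model_comparison(list(chi_square = 120, dof = 101),
                                list(chi_square = 100, dof = 100))
  expect_equal(ft$F, 20)
  expect_equal(ft$p_value, stats::pf(20, 1, 100, lower.tail = FALSE))
  expect_lt(ft$p_value, 1e-4)

  expect_error(f_test_model_comparison(list(chi_square = 90, dof = 100),
                                       list(chi_square = 0, dof = 99)),
               "positive")
  expect_error(f_test_model_comparison(list(chi_square = 90, dof = 99),
                                       list(chi_square = 80, dof = 100)),
               "nested")
})

test_that("mean molecular area reproduces the bilayer benchmarks", {
  # DMPC tails: V = 782, leaflet 13.6 A at 96 % coverage
  expect_equal(layer_mma(27.2 / 2, 0.96, 782), 59.9, tolerance = 0.01)
  # PC heads agree within the quoted +/- 2 A^2
  expect_lt(abs(layer_mma(9.0, 0.62, 319) - layer_mma(27.2 / 2, 0.96, 782)),
            4)
  # exact identity at full coverage
  expect_equal(layer_mma(10, 1, 10 * 47.3), 47.3)
  expect_error(layer_mma(10, 0, 782), "coverage")
})
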