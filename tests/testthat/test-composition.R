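test_that("lipid removal is a signed coverage difference with propagated error", {
  expect_equal(lipid_removal_percent(0.96, 0.90)$value, 6)
  expect_equal(lipid_removal_percent(0.9, 0.9)$value, 0)
  # the mature-HDL scale
  expect_equal(lipid_removal_percent(0.95, 0.55)$value, 40)
  # antisymmetry under swapping before/after
  expect_equal(lipid_removal_percent(0.90, 0.96)$value,
               -lipid_removal_percent(0.96, 0.90)$value)
  expect_equal(lipid_removal_percent(0.96, 0.90, 0.01, 0.01)$sigma,
               100 * sqrt(2) * 0.01)
})

test_that("exchange percentage is affine in the observed SLD with endpoint checks", {
  d <- 6.93; h <- -0.39
  expect_equal(exchange_percent(d, d, h)$value, 0)
  expect_equal(exchange_percent(h, d, h)$value, 100)
  expect_equal(exchange_percent((d + h) / 2, d, h)$value, 50)
  # affine: value at a convex combination is the combination of values
  for (f in c(0.1, 0.404, 0.8)) {
    expect_equal(exchange_percent(d + f * (h - d), d, h)$value, 100 * f)
  }
  expect_equal(exchange_percent(4, d, h, sigma = 0.0732)$sigma, 1)
  expect_error(exchange_percent(8.5, d, h), "outside")
  expect_error(exchange_percent(5, d, d), "differ")
})

test_that("protein core fraction interpolates between lipid and protein SLDs", {
  expect_equal(protein_core_fraction(6.93, 6.93, 1.86)$value, 0)
  expect_equal(protein_core_fraction(1.86, 6.93, 1.86)$value, 1)
  expect_equal(protein_core_fraction(6.93 + 0.15 * (1.86 - 6.93),
                                     6.93, 1.86)$value, 0.15)
})

test_that("co-localisation ratio follows the per-area protein volumes", {
  expect_equal(colocalisation_percent(0.2, 30, 0, 28), 100)
  expect_equal(colocalisation_percent(0.1, 28, 0.1, 28), 50)
  expect_equal(colocalisation_percent(0.10, 27.2, 0.04, 28),
               100 * 2.72 / (2.72 + 1.12), tolerance = 1e-12)
  expect_error(colocalisation_percent(0, 27.2, 0, 28), "undefined")
})

test_that("kinetics series reports the three replacement metrics", {
  flat <- data.frame(time = 0:3, phi_solvent = 0.04,
                     tail_sld_dry = 6.93)
  ks <- kinetics_series(flat)
  expect_equal(ks$delta_phi_solvent, rep(0, 4))
  expect_equal(ks$exchange_fraction, rep(0, 4))
  expect_equal(ks$replaced_fraction, rep(0, 4))

  # halving the deuterated fraction at constant lipid content gives 0.5
  half <- data.frame(time = c(0, 1), phi_solvent = 0.04,
                     tail_sld_dry = c(6.93, 6.93 + 0.5 * (-0.39 - 6.93)))
  expect_equal(kinetics_series(half)$replaced_fraction, c(0, 0.5))

  # a step trajectory is reproduced
  step <- data.frame(time = 0:4, phi_solvent = 0.04,
                     tail_sld_dry = c(6.93, 6.93,
                                      rep(6.93 + 0.3 * (-0.39 - 6.93), 3)))
  expect_equal(kinetics_series(step)$exchange_fraction,
               c(0, 0, 0.3, 0.3, 0.3))
  expect_error(kinetics_series(data.frame(time = c(2, 1),
                                          phi_solvent = 0.04,
                                          tail_sld_dry = 6.93)),
               "non-decreasing")
})

test_that("exponential-approach fit recovers plateau and time constant", {
  t <- seq(0, 6, length.out = 13)
  set.seed(42)
  y <- 0.404 * (1 - exp(-t / 2)) + rnorm(13, 0, 0.005)
  k <- fit_kinetic_plateau(t, y)
  expect_lt(abs(k$plateau - 0.404), 0.03)
  expect_lt(abs(k$tau - 2), 0.5)
})

test_that("cholesterol specificity verdict follows the 2-sigma rule", {
  borderline <- cholesterol_specificity(list(value = 30.0, sigma = 0.5),
                                        list(value = 29.1, sigma = 0.5))
  expect_equal(borderline$difference, 0.9)
  expect_equal(borderline$sigma, sqrt(0.5), tolerance = 1e-12)
  expect_false(borderline$significant)

  same <- cholesterol_specificity(list(value = 25, sigma = 1),
                                  list(value = 25, sigma = 1))
  expect_equal(same$difference, 0)
  expect_false(same$significant)

  clear <- cholesterol_specificity(list(value = 40, sigma = 1),
                                   list(value = 20, sigma = 1))
  expect_equal(clear$difference, 20)
  expect_equal(clear$sigma, sqrt(2), tolerance = 1e-12)
  expect_true(clear$significant)
})

test_that("volume-to-mole fraction conversion respects molecular volumes", {
  expect_equal(exchange_mole_fraction(0.5, 782, 782), 0.5)
  expect_gt(exchange_mole_fraction(0.5, 391, 782), 0.5)
  expect_equal(exchange_mole_fraction(0, 630, 782), 0)
  expect_equal(exchange_mole_fraction(1, 630, 782), 1)
})

test_that("composition report bundles quantities with uncertainties", {
  rep <- composition_report(
    lipid_removal = lipid_removal_percent(0.96, 0.90, 0.01, 0.01),
    lipid_exchange = exchange_percent(3.973, 6.93, -0.39, sigma = 0.02),
    protein_core = list(value = 0.10, sigma = 0.01),
    protein_top = list(value = 0.04, sigma = 0.01),
    core_thickness = 27.2, top_thickness = 28)
  expect_s3_class(rep, "composition_report")
  expect_setequal(rep$quantity,
                  c("lipid_removal", "lipid_exchange",
                    "protein_core_fraction", "protein_top_fraction",
                    "colocalisation"))
  col <- rep$value[rep$quantity == "colocalisation"]
  expect_equal(col, 70.8, tolerance = 0.01)
  p <- tempfile(fileext = ".tsv")
  write_composition_report(rep, p)
  back <- read.delim(p)
  expect_equal(back$value, rep$value, tolerance = 1e-12)
})
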