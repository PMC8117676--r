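test_that("SLB stacks are assembled in physical order with solvent mixing", {
  m <- ddmpc_model()
  st <- build_slb_stack(m, solvent_sld(1), 1)
  nm <- vapply(st$slabs, `[[`, character(1), "name")
  expect_equal(nm, c("oxide", "head_inner", "tails", "head_outer"))
  # tail slab SLD is the coverage-weighted mixture with d-TBS
  eff <- stack_slab_slds(st)
  expect_equal(eff[nm == "tails"], 0.96 * 6.93 + 0.04 * 6.36,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(st$fronting_sld, 2.07)
  expect_equal(st$backing_sld, 6.36)

  # gap and top layer appear only when their thickness is positive
  m5 <- ddmpc_model(gap_thickness = 5, top_layer_thickness = 28,
                    top_layer_coverage = 0.04)
  st5 <- build_slb_stack(m5, solvent_sld(0), 0)
  expect_equal(vapply(st5$slabs, `[[`, character(1), "name"),
               c("oxide", "gap", "head_inner", "tails", "head_outer", "top"))
  # top layer protein SLD follows the labile-H endpoints
  expect_equal(st5$slabs[[6]]$sld, 1.86)

  # full coverage: slab SLDs equal material SLDs exactly
  m1 <- ddmpc_model(head_coverage = 1, tail_coverage = 1, oxide_solvation = 0)
  st1 <- build_slb_stack(m1, 3.3, 0.5)
  expect_equal(stack_slab_slds(st1), c(3.47, 1.84, 6.93, 1.84))

  # zero coverage: membrane invisible (every slab SLD equals solvent)
  m0 <- ddmpc_model(head_coverage = 0, tail_coverage = 0, oxide_solvation = 1)
  st0 <- build_slb_stack(m0, 4.5, 0.7)
  expect_equal(stack_slab_slds(st0), rep(4.5, 4))

  expect_error(slb_model(tail_thickness = -1), "thickness")
  expect_error(slb_model(head_coverage = 1.2), "coverage")
})

test_that("Abeles reflectivity matches closed forms and physical limits", {
  q <- exp(seq(log(0.005), log(0.3), length.out = 60))

  # uniform medium reflects nothing
  stu <- layer_stack(3.2, list(slab(20, 3.2), slab(11, 3.2)), 3.2)
  expect_lt(max(reflectivity_abeles(stu, q)), 1e-12)

  # total reflection below the Si|D2O critical edge
  st <- layer_stack(2.07, list(), 6.36)
  qc <- critical_edge(2.07, 6.36)
  expect_equal(qc, 4 * sqrt(pi * 4.29e-6), tolerance = 1e-12)
  qlow <- q[q < 0.95 * qc]
  expect_equal(reflectivity_abeles(st, qlow), rep(1, length(qlow)),
               tolerance = 1e-9)

  # Fresnel closed form above the edge
  expect_equal(reflectivity_abeles(st, 0.05), fresnel_R(0.05, 2.07, 6.36),
               tolerance = 1e-10)

  # no edge when the contrast is non-positive
  expect_identical(critical_edge(2.07, 2.07), 0)
  expect_identical(critical_edge(2.07, -0.56), 0)

  # energy bound on a rough, solvated stack
  m <- ddmpc_model(roughness_common = 5, substrate_roughness = 4)
  for (x in c(0, 0.38, 1)) {
    R <- reflectivity_abeles(build_slb_stack(m, solvent_sld(x), x), q)
    expect_true(all(R >= 0 & R <= 1))
    expect_false(anyNA(R))
  }
})

test_that("Abeles agrees with an independent Parratt recursion", {
  set.seed(11)
  q <- exp(seq(log(0.008), log(0.3), length.out = 50))
  for (rep in 1:30) {
    st <- random_stack()
    Ra <- reflectivity_abeles(st, q)
    Rp <- parratt_reflectivity(
      st$fronting_sld, stack_slab_slds(st),
      vapply(st$slabs, `[[`, numeric(1), "thickness"),
      vapply(st$slabs, `[[`, numeric(1), "roughness"),
      st$backing_sld, st$backing_roughness, q)
    expect_lt(max(abs(Ra - Rp) / pmax(Rp, 1e-300)), 1e-10)
  }
})

test_that("reflection from either side of a lossless stack is reciprocal", {
  # reversing the stack and matching the normal energy (same k_z^2 - 4 pi rho)
  # must give identical reflectivity for absorption-free media
  qA <- seq(0.02, 0.3, length.out = 40)
  st <- layer_stack(0.5, list(slab(30, 4), slab(20, 1.5), slab(35, 3)), 2.5)
  rev_st <- layer_stack(2.5, list(slab(35, 3), slab(20, 1.5), slab(30, 4)),
                        0.5)
  qB <- 2 * sqrt((qA / 2)^2 - 4 * pi * (2.5 - 0.5) * 1e-6)
  expect_equal(reflectivity_abeles(st, qA), reflectivity_abeles(rev_st, qB),
               tolerance = 1e-10)
})

test_that("resolution smearing preserves constants, is linear and matches a dense convolution", {
  q <- exp(seq(log(0.012), log(0.25), length.out = 40))
  fres <- function(qq) fresnel_R(qq, 2.07, 6.36)

  # zero resolution is the identity
  expect_identical(smear_gaussian(q, R = fres(q), dq_over_q = 0), fres(q))

  # constants are preserved exactly (weights renormalised)
  expect_equal(smear_gaussian(q, model = function(qq) rep(0.37, length(qq)),
                              dq_over_q = 0.07),
               rep(0.37, length(q)), tolerance = 1e-14)

  # linearity
  f1 <- function(qq) fres(qq)
  f2 <- function(qq) 1e-4 / qq
  s12 <- smear_gaussian(q, model = function(qq) f1(qq) + 2 * f2(qq),
                        dq_over_q = 0.07)
  expect_equal(s12,
               smear_gaussian(q, model = f1, dq_over_q = 0.07) +
                 2 * smear_gaussian(q, model = f2, dq_over_q = 0.07),
               tolerance = 1e-12)

  # 7 % smearing of the Fresnel curve vs brute-force dense convolution:
  # 0.1 % away from the critical edge, 1 % at the edge itself where the
  # reflectivity has a derivative kink that limits fixed-order quadrature
  sm <- smear_gaussian(q, model = fres, dq_over_q = 0.07)
  dense <- dense_smear(q, fres, 0.07 * q)
  rel <- abs(sm - dense) / dense
  qc <- critical_edge(2.07, 6.36)
  near_edge <- abs(q - qc) < 3.5 * 0.07 * q / 2.355
  expect_lt(max(rel[!near_edge]), 1e-3)
  expect_lt(max(rel), 1e-2)
})
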