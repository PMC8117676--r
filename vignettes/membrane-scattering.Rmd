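---
title: "Quantifying apolipoprotein-membrane interaction from neutron scattering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apolipoprotein-membrane interaction from neutron scattering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipidscatter)
```

## The problem

Apolipoprotein E (ApoE) and the reconstituted high-density-lipoprotein
(rHDL) nanodiscs it forms interact with cellular membranes by inserting
protein, removing lipids and exchanging lipids. When the membrane is a
supported lipid bilayer (SLB) with deuterated acyl chains and the incoming
protein or particle is hydrogenous, neutron scattering can separate these
three processes: specular neutron reflectometry (NR) measured in several
H2O/D2O buffer contrasts constrains a depth profile of the interface, and
small-angle neutron scattering (SANS) determines the size and shape of the
free nanodiscs. This package implements the full analysis chain: the slab
reflectivity model and its multi-contrast co-refinement, the decomposition
of fitted bilayer parameters into removal/exchange/insertion percentages,
an elliptical core-shell bicelle form factor for the nanodiscs, the
geometric bookkeeping that converts a fitted disc shape into molecule
counts, and a synthetic-data generator so the whole pipeline can be
exercised against known ground truth.

## The reflectivity model

The interface is modelled as a stack of homogeneous slabs between
semi-infinite silicon and bulk solvent. Reflectivity is computed exactly
with the Abeles transfer-matrix recursion; interfacial roughness enters
through Nevot-Croce factors `exp(-2 k_n k_{n+1} sigma^2)` applied to each
Fresnel coefficient. (Whether the original slab fits used Nevot-Croce
damping or error-function profile slicing is not documented for the
software they were made with; Nevot-Croce is the standard choice at these
roughnesses, below about 5 Angstrom, where the two conventions are
indistinguishable at 7 % resolution.) The test suite holds the
implementation to an independent Parratt recursion at 1e-10 relative error
and to the closed-form Fresnel curve of a bare interface.

The bilayer is parameterised symmetrically (heads-tails-heads): both
headgroup layers share one thickness, coverage and SLD, and one roughness
applies to every bilayer interface. A solvent gap below the bilayer and a
protein/particle layer on top are included when their thickness is
non-zero, giving the four- or five-layer models used for supported
membranes. Each slab's SLD is the coverage-weighted mix of dry material and
solvent. Units are fixed throughout: lengths in Angstrom, SLDs in 1e-6
Angstrom^-2, volumes in Angstrom^3, q in Angstrom^-1.

Instrument resolution is applied per point as a Gaussian of fwhm `dq`,
evaluated by 17-node Gauss-Legendre quadrature over +/- 3.5 standard
deviations with renormalised weights, so smearing is linear and preserves
constants exactly. Near the critical edge, where R(q) has a derivative
kink, fixed-order quadrature agrees with a dense convolution to about 1 %;
everywhere else to better than 0.1 %.

## Co-refinement, uncertainties and model comparison

One structural model is fitted simultaneously to all solvent contrasts;
only a scale (bounded to [0.9, 1.1]) and a flat background (up to 1e-5) are
allowed to differ per contrast, typical residual imperfections of reduced
reflectivity data. The objective is the joint chi-square. Optimisation uses
a small seeded differential-evolution optimiser (rand/1/bin, population 15
per free parameter, relative tolerance 1e-8) followed by a derivative-free
local polish; given a seed the result is bit-reproducible. Parameter
uncertainties come from Monte-Carlo resampling: each resample perturbs
every data point by its quoted 1-sigma uncertainty and re-polishes from the
best fit; the parameter sigma is the standard deviation over resamples.
Nested models are compared with an F-test on the chi-square drop, assuming
normal errors.

Two physically motivated constraints are built in. First, the mean
molecular area (MMA = V / (t_leaflet * coverage)) must agree between the
headgroup and tail regions; this is enforced as a soft penalty when the two
areas differ by more than 5 %, rather than by reparameterising, since the
two fitting styles are known to give equivalent results for these systems.
Second, post-interaction refits start from the pristine-bilayer parameters
and free only the tail SLD and the coverages; thicknesses are freed only
when an F-test justifies the extra parameters at p = 0.05. Significance is
conventionally reported at p = 0.1 and p = 0.05.

## Composition decomposition

The decomposition uses the fact that SLDs mix by volume. With deuterated
tail SLD `rho_d` and hydrogenous tail SLD `rho_h`, a fitted dry tail SLD
`rho_obs` gives the exchanged volume fraction
`(rho_d - rho_obs) / (rho_d - rho_h)`; lipid removal is the signed coverage
difference before/after incubation; for lipid-free protein incubations the
same interpolation against the protein SLD gives the inserted protein
fraction. The dry tail region is treated as a two-component mixture in
either case - deuterated plus hydrogenous lipid for rHDL incubations
(protein contribution to the core neglected, consistent with the roughly
1 % particle coverage resolved on top), deuterated lipid plus protein for
lipid-free incubations - because three contrasts determine no more than a
two-component split. Co-localisation between core and top layers uses the
equal-area slab ratio `phi_core t_core / (phi_core t_core + phi_top t_top)`.
All percentages carry first-order propagated uncertainties.

Kinetics runs are measured in the H2O buffer only (best contrast against
deuterated tails), so per-slice fits fix the structure at its
pre-incubation values and free only the tail SLD, tail solvation and,
where present, the top-layer coverage. Because a single scalar cannot
faithfully summarise "replacement", the slice table reports three metrics:
the solvent-fraction change, the exchanged fraction from the dry SLD, and
the combined replaced-lipid fraction
`1 - phi_lipid(t) x_d(t) / (phi_lipid(0) x_d(0))`.

## The nanodisc SANS model

The free rHDL particle is modelled as an elliptical core-shell bicelle:
an elliptical hydrophobic core (half-height L/2) capped by two headgroup
face layers and encircled by a protein rim whose outer boundary is the
ellipse with semi-axes `(r_minor + d_belt, ellipticity * r_minor + d_belt)`
- the standard constant-width belt approximation. The face layers sit
inside the rim. The scattering amplitude is the superposition of three
coaxial elliptical cylinders with contrast steps rim-solvent, face-rim and
core-face; each cylinder contributes
`V sinc(q h cos a) 2 J1(u)/u` with `u = q r(psi) sin a`. Orientation
averaging uses Gauss-Legendre quadrature over the tilt (weight sin a) and
the in-plane azimuth, 48 x 24 nodes by default and 32 x 16 inside fits;
both choices are converged to much better than 0.1 % for discs of this
size, and orders below 8 are refused. The forward-scattering identity
`I(0) V_outer / scale = (sum drho V)^2` and a brute-force numeric
integration of the circular case anchor the implementation in the test
suite.

"Radius" for these discs means the minor semi-axis of the lipid core: this
is the only reading under which twice (radius + belt) and twice
(ellipticity x radius + belt) reproduce the quoted short and long disc
diameters exactly. The core thickness is held at 28 Angstrom, the value
these particles refine to and consistent with the NR tail thickness.
Headgroup faces carry 30 % hydration by default. Protein and other
labile-hydrogen materials interpolate their SLD linearly between H2O- and
D2O-buffer endpoints (1.86 and 3.11 x 1e-6 A^-2 for the protein, the D2O
endpoint folding in 90 % exchange efficiency); solving for the solvent that
matches the protein reproduces the 42 % d-TBS protein-matched buffer, just
as the plain mixing rule puts the silicon match point at 38 % D2O. No size
polydispersity is fitted, and wavelength smearing (9 % fwhm where
applicable) is off by default but switchable - reduced SANS data of this
kind are commonly fitted either way.

## The geometry chain

From a fitted disc shape the package derives the quantities a structural
model must explain. The circumference uses the root-mean-square-of-semi-axes
form `2 pi sqrt(((r + d)^2 + (e r + d)^2) / 2)`; dividing by the 1.5
Angstrom helical rise per residue counts the residues in contact with the
rim, and a 299-residue protein bounds a single belt at about 448.5
Angstrom. The area per lipid follows from the chain volume and the fixed
core thickness (`2 V / L`), the lipid count per leaflet from the core
ellipse area, and the protein count from the ceiling of total rim length
(two belts, one per leaflet) over the single-protein maximum - a partial
belt still needs a whole protein. Counts round half away from zero. The
molecular volumes (DMPC chains 782, PC head 319 Angstrom^3) are shared with
the reflectometry MMA computation so the two techniques remain
commensurable; the dPOPC chain volume, not fixed by the sources above, is
taken as 925 Angstrom^3, a standard value for d67 chains at 37 C.

## The synthetic-data generator

The generator is the package's stand-in for instrument data and defines
the study conditions for every recovery test. NR curves use 120 log-spaced
points over 0.01-0.3 A^-1 with dq/q = 7 % (fwhm) in three contrasts (h-TBS,
d-TBS, and 38 % d-TBS matching silicon); SANS curves use 150 log-spaced
points over 0.002-0.3 A^-1 in h-TBS, d-TBS and the 42 % protein-matched
buffer. Noise is Gaussian with honest quoted uncertainties - 3 % relative
(floor 1e-8) for NR, 2 % relative for SANS with flat incoherent backgrounds
interpolated between 0.05 (h-TBS) and 0.005 cm^-1 (d-TBS) - choices
representative of well-reduced data from these instrument classes, which
the sources do not specify. Output is byte-deterministic given the seed,
and the generated pulls are verified standard normal.

What the generator does not emulate: multiple-angle stitching artefacts,
footprint and gravity corrections, off-specular background, detector
non-uniformity, inter-particle structure factor, or polydispersity.
Passing recovery tests therefore demonstrate that the estimators are
unbiased and correctly weighted under the stated noise model, not that
every systematic of real reduced data is handled.

## Problem sizes and numerical choices

The recovery suites run at sizes chosen to exercise the estimators while
keeping the full test run comfortable on a single CPU: 60-120 point q
grids, differential-evolution budgets of order 100 generations,
12-20 Monte-Carlo resamples, and round-trip grids over exchanged fractions
of 10-40 % with removals of 0-5 %. Degenerate inputs are handled
explicitly: zero-thickness slabs are dropped before matrix evaluation,
zero resolution short-circuits to the identity, zero quoted uncertainties
yield zero Monte-Carlo sigma without refitting (weights for chi-square are
still refused), and a fitted tail SLD outside the mixing interval by more
than 2 % of its width raises an error as a model-mis-specification signal
rather than silently clipping.

## A worked example

```{r example, eval = FALSE}
# geometry chain for the larger disc
nanodisc_geometry_report(r_minor = 42.0, ellipticity = 1.4, d_belt = 11.0)

# synthetic three-contrast experiment and full recovery
truth <- slb_model(tail_sld_material = 6.93 + 0.404 * (-0.39 - 6.93))
sim <- simulate_reflectivity(nr_recipe(truth = truth, seed = 42))
fit <- fit_global(sim$datasets, slb_model(),
                  free = c("tail_sld_material", "tail_coverage"),
                  bounds = list(tail_sld_material = c(-0.39, 6.93),
                                tail_coverage = c(0.5, 1)), seed = 7)
fit <- mc_uncertainty(fit, sim$datasets, n_resamples = 20, seed = 8)
exchange_percent(fit$parameters[["tail_sld_material"]], 6.93, -0.39,
                 sigma = fit$sigma[["tail_sld_material"]])
```

## Known limitations

NR cannot distinguish one protein bent across core and headgroups from
separate proteins occupying each region, and no attempt is made to. The
two-component SLD decomposition is the most three contrasts can determine;
if protein insertion and lipid exchange co-occur in an rHDL incubation
their core contributions are conflated. Single-contrast kinetics slices
constrain only the freed parameters, and the geometric protein count is a
feasibility ceiling, not a measurement - cross-checks against phosphate
analysis or similar are advisable on real data.
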