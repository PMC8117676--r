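#' A homogeneous slab
#'
#' One layer of a stratified interfacial model: thickness, real and imaginary
#' scattering length density, Gaussian roughness to the previous (incoming
#' side) interface, and solvent volume fraction. The effective SLD used in
#' reflectivity calculations is
#' `(1 - solvent_fraction) * sld + solvent_fraction * sld_solvent`.
#'
#' @param thickness layer thickness, Angstrom (>= 0)
#' @param sld real SLD of the dry material, 1e-6 A^-2
#' @param isld imaginary SLD, 1e-6 A^-2
#' @param roughness roughness to the previous interface, Angstrom (>= 0)
#' @param solvent_fraction solvent volume fraction in `[0, 1]`
#' @param name optional label
#' @return an object of class `slab`
#' @export
slab <- function(thickness, sld, isld = 0, roughness = 0,
                 solvent_fraction = 0, name = "") {
  if (thickness < 0) stop("slab thickness must be >= 0")
  if (roughness < 0) stop("slab roughness must be >= 0")
  if (solvent_fraction < 0 || solvent_fraction > 1)
    stop("solvent_fraction must lie in [0, 1]")
  structure(list(thickness = thickness, sld = sld, isld = isld,
                 roughness = roughness, solvent_fraction = solvent_fraction,
                 name = name),
            class = "slab")
}

#' An ordered stack of slabs between two semi-infinite media
#'
#' @param fronting_sld SLD of the incoming semi-infinite medium (silicon for
#'   a solid-liquid cell), 1e-6 A^-2
#' @param slabs list of [slab()] objects, ordered from fronting to backing
#' @param backing_sld SLD of the semi-infinite backing (bulk solvent)
#' @param backing_roughness roughness of the last slab / backing interface,
#'   Angstrom
#' @return an object of class `layer_stack`
#' @export
layer_stack <- function(fronting_sld, slabs, backing_sld,
                        backing_roughness = 0) {
  stopifnot(is.list(slabs))
  if (length(slabs) && !all(vapply(slabs, inherits, TRUE, "slab")))
    stop("all elements of `slabs` must be slab objects")
  structure(list(fronting_sld = fronting_sld, slabs = slabs,
                 backing_sld = backing_sld,
                 backing_roughness = backing_roughness),
            class = "layer_stack")
}

#' Effective (solvent-mixed) slab SLDs of a stack
#'
#' @param stack a [layer_stack()]
#' @return numeric vector of effective slab SLDs, 1e-6 A^-2
#' @export
stack_slab_slds <- function(stack) {
  vapply(stack$slabs, function(s) {
    (1 - s$solvent_fraction) * s$sld + s$solvent_fraction * stack$backing_sld
  }, numeric(1))
}

#' Symmetric supported-lipid-bilayer fit model
#'
#' The heads-tails-heads parameterisation shared across solvent contrasts:
#' both headgroup layers share one thickness, coverage and material SLD, and
#' one roughness applies to all bilayer interfaces. Optional components are a
#' solvent gap between the oxide and the bilayer and a protein/rHDL layer on
#' top of the bilayer; either is omitted when its thickness is zero.
#' Coverage is the material volume fraction of a layer (1 - solvent fraction).
#'
#' @param oxide_thickness,oxide_solvation,oxide_roughness silicon-oxide layer
#'   parameters (Angstrom / fraction / Angstrom); oxide SLD fixed at the
#'   silica table value
#' @param gap_thickness thickness of an optional pure-solvent gap, Angstrom
#' @param head_thickness,head_coverage,head_sld_material headgroup layer
#'   thickness (A), coverage in `[0, 1]`, dry SLD (1e-6 A^-2)
#' @param tail_thickness,tail_coverage,tail_sld_material tail (hydrophobic
#'   core) region, full bilayer-core thickness (both leaflets)
#' @param roughness_common single roughness for every bilayer interface, A
#' @param top_layer_thickness,top_layer_coverage,top_layer_sld_h2o,top_layer_sld_d2o
#'   optional layer of protein or bound particles on top of the bilayer; its
#'   SLD follows the labile-H rule between the two endpoints
#' @param substrate_roughness silicon/oxide roughness, Angstrom
#' @return an object of class `slb_model` (named list)
#' @export
slb_model <- function(oxide_thickness = 12, oxide_solvation = 0.10,
                      oxide_roughness = 3, substrate_roughness = 3,
                      gap_thickness = 0,
                      head_thickness = 9.0, head_coverage = 0.62,
                      head_sld_material = 1.84,
                      tail_thickness = 27.2, tail_coverage = 0.96,
                      tail_sld_material = 6.93,
                      roughness_common = 3,
                      top_layer_thickness = 0, top_layer_coverage = 0,
                      top_layer_sld_h2o = 1.86, top_layer_sld_d2o = 3.11) {
  m <- list(oxide_thickness = oxide_thickness, oxide_solvation = oxide_solvation,
            oxide_roughness = oxide_roughness,
            substrate_roughness = substrate_roughness,
            gap_thickness = gap_thickness,
            head_thickness = head_thickness, head_coverage = head_coverage,
            head_sld_material = head_sld_material,
            tail_thickness = tail_thickness, tail_coverage = tail_coverage,
            tail_sld_material = tail_sld_material,
            roughness_common = roughness_common,
            top_layer_thickness = top_layer_thickness,
            top_layer_coverage = top_layer_coverage,
            top_layer_sld_h2o = top_layer_sld_h2o,
            top_layer_sld_d2o = top_layer_sld_d2o)
  validate_slb_model(m)
  structure(m, class = "slb_model")
}

validate_slb_model <- function(m) {
  thick <- c(m$oxide_thickness, m$gap_thickness, m$head_thickness,
             m$tail_thickness, m$top_layer_thickness)
  if (any(thick < 0)) stop("negative thickness in SLB model")
  cov <- c(m$head_coverage, m$tail_coverage, m$top_layer_coverage,
           1 - m$oxide_solvation)
  if (any(cov < 0 | cov > 1)) stop("coverage out of [0, 1] in SLB model")
  if (m$roughness_common < 0 || m$substrate_roughness < 0 ||
      m$oxide_roughness < 0) stop("negative roughness in SLB model")
  invisible(m)
}

#' Build a layer stack from an SLB model and a solvent contrast
#'
#' Stack order is Si | SiO2 | (gap) | heads | tails | heads | (top layer) |
#' solvent. Each slab SLD is solvent-mixed according to its coverage; the gap
#' and top layer are omitted when their thickness is zero. The top-layer dry
#' SLD follows the labile-hydrogen rule between its H2O and D2O endpoints.
#'
#' @param model an [slb_model()]
#' @param solvent_sld bulk solvent SLD, 1e-6 A^-2
#' @param d2o_fraction buffer D2O fraction, used for the top-layer protein
#'   SLD; if `NULL` it is inferred from `solvent_sld` by inverting the
#'   solvent mixing rule
#' @param materials materials table for the substrate SLDs
#' @return a [layer_stack()]
#' @export
#' @examples
#' m <- slb_model()                       # Table-style dDMPC bilayer
#' build_slb_stack(m, solvent_sld(1), 1)  # in d-TBS
build_slb_stack <- function(model, solvent_sld, d2o_fraction = NULL,
                            materials = default_materials()) {
  validate_slb_model(model)
  if (is.null(d2o_fraction)) d2o_fraction <- match_point(solvent_sld, materials)
  slabs <- list(
    slab(model$oxide_thickness, material_sld("silica", d2o_fraction, materials),
         roughness = model$substrate_roughness,
         solvent_fraction = model$oxide_solvation, name = "oxide"))
  if (model$gap_thickness > 0) {
    slabs <- c(slabs, list(
      slab(model$gap_thickness, 0, roughness = model$oxide_roughness,
           solvent_fraction = 1, name = "gap")))
  }
  slabs <- c(slabs, list(
    slab(model$head_thickness, model$head_sld_material,
         roughness = model$oxide_roughness,
         solvent_fraction = 1 - model$head_coverage, name = "head_inner"),
    slab(model$tail_thickness, model$tail_sld_material,
         roughness = model$roughness_common,
         solvent_fraction = 1 - model$tail_coverage, name = "tails"),
    slab(model$head_thickness, model$head_sld_material,
         roughness = model$roughness_common,
         solvent_fraction = 1 - model$head_coverage, name = "head_outer")))
  if (model$top_layer_thickness > 0) {
    top_sld <- model$top_layer_sld_h2o +
      d2o_fraction * (model$top_layer_sld_d2o - model$top_layer_sld_h2o)
    slabs <- c(slabs, list(
      slab(model$top_layer_thickness, top_sld,
           roughness = model$roughness_common,
           solvent_fraction = 1 - model$top_layer_coverage, name = "top")))
  }
  layer_stack(material_sld("silicon", d2o_fraction, materials), slabs,
              solvent_sld, backing_roughness = model$roughness_common)
}

#' Critical momentum transfer of total external reflection
#'
#' `q_c = 4 sqrt(pi * (rho_backing - rho_fronting))` with SLDs in true A^-2.
#' Returns 0 when the SLD contrast is non-positive (no total-reflection edge).
#'
#' @param fronting_sld,backing_sld SLDs in 1e-6 A^-2
#' @return q_c in A^-1
#' @export
#' @examples
#' critical_edge(2.07, 6.36)  # Si against D2O: ~0.01468
critical_edge <- function(fronting_sld, backing_sld) {
  drho <- (backing_sld - fronting_sld) * 1e-6
  if (drho <= 0) return(0)
  4 * sqrt(pi * drho)
}
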