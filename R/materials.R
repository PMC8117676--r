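#' Default materials table
#'
#' Scattering length densities (SLD, units of 1e-6 Angstrom^-2) and molecular
#' volumes (Angstrom^3) for the components of deuterated supported lipid
#' bilayers and apolipoprotein nanodiscs. Solvent-dependent SLDs (labile
#' hydrogen exchange) are encoded as distinct endpoints in pure H2O and pure
#' D2O buffer; materials without exchangeable hydrogens have equal endpoints.
#' The protein D2O endpoint folds in a 90 percent labile-exchange efficiency.
#'
#' @return A data.frame with columns `name`, `sld_h2o`, `sld_d2o` (1e-6 A^-2)
#'   and `volume` (A^3, `NA` where not needed).
#' @export
#' @examples
#' default_materials()
default_materials <- function() {
  data.frame(
    name = c("water", "silicon", "silica", "dDMPC_tails", "hDMPC_tails",
             "dPOPC_tails", "pc_head", "h_cholesterol", "d_cholesterol_mo",
             "protein"),
    sld_h2o = c(-0.56, 2.07, 3.47, 6.93, -0.39, 6.40, 1.84, 0.21, 6.36, 1.86),
    sld_d2o = c(6.36, 2.07, 3.47, 6.93, -0.39, 6.40, 1.84, 0.21, 6.36, 3.11),
    volume  = c(30, NA, NA, 782, 782, 925, 319, 630, 630, NA),
    stringsAsFactors = FALSE
  )
}

#' SLD of a material at a given solvent deuteration
#'
#' Interpolates linearly between the H2O- and D2O-buffer endpoints, which
#' implements the labile-hydrogen exchange rule: non-exchanging materials are
#' constant, the protein SLD rises with the D2O fraction of the buffer.
#'
#' @param name material name in `materials$name`
#' @param d2o_fraction D2O volume fraction of the buffer, in `[0, 1]`
#' @param materials a materials table, see [default_materials()]
#' @return SLD in 1e-6 A^-2
#' @export
material_sld <- function(name, d2o_fraction, materials = default_materials()) {
  stopifnot(d2o_fraction >= 0, d2o_fraction <= 1)
  i <- match(name, materials$name)
  if (is.na(i)) stop("unknown material: ", name)
  materials$sld_h2o[i] + d2o_fraction * (materials$sld_d2o[i] - materials$sld_h2o[i])
}

#' Molecular volume of a material
#' @inheritParams material_sld
#' @return volume in A^3
#' @export
material_volume <- function(name, materials = default_materials()) {
  i <- match(name, materials$name)
  if (is.na(i)) stop("unknown material: ", name)
  materials$volume[i]
}

#' Solvent SLD from the buffer D2O fraction
#'
#' Linear H2O/D2O mixing; buffer salts are neglected. An x percent d-TBS
#' buffer has SLD `x * rho_D2O + (1 - x) * rho_H2O`.
#'
#' @inheritParams material_sld
#' @return SLD in 1e-6 A^-2
#' @export
#' @examples
#' solvent_sld(0)     # h-TBS
#' solvent_sld(1)     # d-TBS
#' solvent_sld(0.38)  # cmSi, matches silicon at 2.07
solvent_sld <- function(d2o_fraction, materials = default_materials()) {
  material_sld("water", d2o_fraction, materials)
}

#' D2O fraction at which the solvent matches a target SLD
#'
#' Inverse of [solvent_sld()]. Used to locate contrast-match points, e.g. the
#' 38 percent d-TBS buffer that matches the silicon substrate.
#'
#' @param target_sld SLD to match, 1e-6 A^-2; must lie between the H2O and
#'   D2O buffer SLDs
#' @param materials a materials table
#' @return D2O fraction in `[0, 1]`
#' @export
#' @examples
#' match_point(2.07)  # silicon: 0.38
match_point <- function(target_sld, materials = default_materials()) {
  lo <- material_sld("water", 0, materials)
  hi <- material_sld("water", 1, materials)
  if (target_sld < min(lo, hi) || target_sld > max(lo, hi))
    stop("target SLD ", target_sld, " outside the solvent range [", lo, ", ", hi, "]")
  (target_sld - lo) / (hi - lo)
}

#' Match point of a material with labile hydrogens
#'
#' Solves for the buffer D2O fraction at which the material SLD (itself
#' solvent-dependent through labile-H exchange) equals the solvent SLD.
#' For the default protein entry this lands at ~0.43, the basis of the
#' 42 percent d-TBS protein-matched buffer.
#'
#' @inheritParams material_sld
#' @return D2O fraction
#' @export
labile_match_point <- function(name, materials = default_materials()) {
  i <- match(name, materials$name)
  if (is.na(i)) stop("unknown material: ", name)
  w <- match("water", materials$name)
  num <- materials$sld_h2o[i] - materials$sld_h2o[w]
  den <- (materials$sld_d2o[w] - materials$sld_h2o[w]) -
         (materials$sld_d2o[i] - materials$sld_h2o[i])
  x <- num / den
  if (x < 0 || x > 1) stop("no match point within [0, 1] for ", name)
  x
}
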