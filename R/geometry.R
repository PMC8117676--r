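#' Nanodisc circumference including ellipticity
#'
#' Root-mean-square-of-semi-axes perimeter of the disc outer envelope:
#' `2 pi sqrt(((r_minor + d_belt)^2 + (ellipticity r_minor + d_belt)^2) / 2)`.
#' Reduces to the exact circle perimeter at ellipticity 1 and zero belt.
#'
#' @param r_minor minor semi-axis of the lipid core, Angstrom (>= 0)
#' @param ellipticity axial ratio, >= 1
#' @param d_belt protein rim width, Angstrom (>= 0)
#' @return circumference, Angstrom
#' @export
#' @examples
#' eq1_circumference(42.0, 1.4, 11.0)  # ~389
eq1_circumference <- function(r_minor, ellipticity, d_belt) {
  stopifnot(r_minor >= 0, d_belt >= 0, ellipticity >= 1)
  a <- r_minor + d_belt
  b <- ellipticity * r_minor + d_belt
  2 * pi * sqrt((a^2 + b^2) / 2)
}

# round half away from zero (commercial rounding for molecule counts)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Number of amino-acid residues in contact with the disc rim
#'
#' `round(circumference / rise_per_residue)` with an average helical rise of
#' 1.5 Angstrom per residue.
#'
#' @param circumference Angstrom, > 0
#' @param rise_per_residue Angstrom per residue
#' @return integer residue count
#' @export
residues_in_contact <- function(circumference, rise_per_residue = 1.5) {
  stopifnot(circumference > 0, rise_per_residue > 0)
  as.integer(round_half_away(circumference / rise_per_residue))
}

#' Maximum belt circumference a single protein can cover
#'
#' `n_residues * rise`: with 299 residues per ApoE molecule at 1.5 Angstrom
#' per residue this is ~448 Angstrom.
#'
#' @param n_residues residues per protein
#' @param rise_per_residue Angstrom per residue
#' @return Angstrom
#' @export
max_belt_circumference <- function(n_residues = 299, rise_per_residue = 1.5) {
  stopifnot(n_residues > 0, rise_per_residue > 0)
  n_residues * rise_per_residue
}

#' Area per lipid from the chain volume and core thickness
#'
#' Per-leaflet prism: `V_chain = APL * L / 2`, so `APL = 2 V_chain / L`.
#'
#' @param chain_volume lipid chain volume, A^3
#' @param core_thickness full bilayer hydrophobic thickness L, Angstrom
#' @return area per lipid, A^2
#' @export
#' @examples
#' area_per_lipid(782, 28)  # ~55.9
area_per_lipid <- function(chain_volume, core_thickness) {
  stopifnot(chain_volume > 0, core_thickness > 0)
  2 * chain_volume / core_thickness
}

#' Lipids per leaflet of the elliptical core
#'
#' `round(pi r_minor (ellipticity r_minor) / APL)`.
#'
#' @param r_minor minor semi-axis, Angstrom
#' @param ellipticity axial ratio
#' @param apl area per lipid, A^2
#' @return integer count
#' @export
lipids_per_leaflet <- function(r_minor, ellipticity, apl) {
  stopifnot(r_minor > 0, ellipticity >= 1, apl > 0)
  as.integer(round_half_away(pi * r_minor * (ellipticity * r_minor) / apl))
}

#' Proteins per disc under the double-belt hypothesis
#'
#' With `n_belts` stacked belts (one per leaflet) the total rim length to
#' cover is `n_belts * circumference`; each protein supplies at most
#' `n_residues * rise` of belt, and a partial belt still requires a whole
#' protein, hence the ceiling.
#'
#' @param circumference Angstrom
#' @param n_residues residues per protein
#' @param rise_per_residue Angstrom per residue
#' @param n_belts number of belts around the rim
#' @return integer count
#' @export
proteins_per_disc <- function(circumference, n_residues = 299,
                              rise_per_residue = 1.5, n_belts = 2) {
  stopifnot(circumference > 0, n_residues > 0, rise_per_residue > 0,
            n_belts > 0)
  as.integer(ceiling(n_belts * circumference /
                     (n_residues * rise_per_residue)))
}

#' Full nanodisc geometry report
#'
#' Runs the derivation chain from the fitted disc parameters to the derived
#' quantities: circumference, short/long axis diameters, residues in
#' contact, maximum single-protein belt length, area per lipid, lipids per
#' leaflet and proteins per disc.
#'
#' @param r_minor,ellipticity,d_belt fitted disc parameters (Angstrom, -, A)
#' @param chain_volume lipid chain volume, A^3
#' @param core_thickness bilayer core thickness, Angstrom
#' @param n_residues residues per protein
#' @param rise_per_residue Angstrom per residue
#' @param n_belts belts per disc
#' @return a list of class `geometry_report`
#' @export
#' @examples
#' nanodisc_geometry_report(42.0, 1.4, 11.0)
nanodisc_geometry_report <- function(r_minor, ellipticity, d_belt,
                                     chain_volume = 782, core_thickness = 28,
                                     n_residues = 299, rise_per_residue = 1.5,
                                     n_belts = 2) {
  circ <- eq1_circumference(r_minor, ellipticity, d_belt)
  apl <- area_per_lipid(chain_volume, core_thickness)
  structure(list(
    r_minor = r_minor, ellipticity = ellipticity, d_belt = d_belt,
    short_axis_diameter = 2 * (r_minor + d_belt),
    long_axis_diameter = 2 * (ellipticity * r_minor + d_belt),
    circumference = circ,
    n_residues_in_contact = residues_in_contact(circ, rise_per_residue),
    max_circumference = max_belt_circumference(n_residues, rise_per_residue),
    area_per_lipid = apl,
    lipids_per_leaflet = lipids_per_leaflet(r_minor, ellipticity, apl),
    proteins_per_disc = proteins_per_disc(circ, n_residues,
                                          rise_per_residue, n_belts)),
    class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("%-28s %s\n", "Radius (minor semi-axis) / A", format(x$r_minor)))
  cat(sprintf("%-28s %s\n", "Ellipticity ratio", format(x$ellipticity)))
  cat(sprintf("%-28s %s\n", "Protein rim thickness / A", format(x$d_belt)))
  cat(sprintf("%-28s %.1f-%.1f\n", "Short-long axis diameter / A",
              x$short_axis_diameter, x$long_axis_diameter))
  cat(sprintf("%-28s %.0f\n", "Disc circumference / A", x$circumference))
  cat(sprintf("%-28s %d\n", "No. amino acids", x$n_residues_in_contact))
  cat(sprintf("%-28s %.1f\n", "Area per lipid / A^2", x$area_per_lipid))
  cat(sprintf("%-28s %d\n", "No. lipids per leaflet", x$lipids_per_leaflet))
  cat(sprintf("%-28s %d\n", "No. proteins per disc", x$proteins_per_disc))
  invisible(x)
}

#' Write a geometry report as a tab-separated table
#' @param report a `geometry_report`
#' @param path output file
#' @export
write_geometry_report <- function(report, path) {
  df <- data.frame(quantity = names(unclass(report)),
                   value = unlist(unclass(report), use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
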