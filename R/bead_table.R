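#' Default bead-type table
#'
#' One row per coarse-grained bead class used by the triskelion amphiphile
#' model: the rigid aromatic core (real and virtual sites), the ether linker,
#' alkyl and terminal sulfonate beads of the hydrophilic arms, the pendant
#' phenyl bead of the hydrophobic arms, the sodium counterion and a water
#' bead.  Radii follow small/tiny Martini-style bead sizes; masses are
#' nominal coarse-grained masses (amu).
#'
#' Scattering contrasts are *excess over displaced solvent* and are the
#' quantity `delta_rho * V` entering the spherical-bead form amplitude:
#' `xray_contrast` in effective electrons (bead electron count minus water
#' electron density times bead volume), `neutron_contrast` in fm (sum of
#' nuclear scattering lengths minus displaced light-water value).  They are
#' nominal working values; replace the columns for quantitative contrast
#' variation work (e.g. D2O solvent).
#'
#' @return A tibble with columns `name`, `role`, `radius` (A), `charge` (e),
#'   `mass` (amu), `xray_contrast` (electrons), `neutron_contrast` (fm).
#' @examples
#' bead_types()
#' @export
bead_types <- function() {
  tibble(
    name = c("TC5e", "TC5v", "TN2a", "SC1", "SQ4n", "TC5", "TQ5", "CL", "W"),
    role = c("core", "core-virtual", "linker", "alkyl", "sulfonate",
             "phenyl", "counterion", "counterion", "solvent"),
    radius = c(1.70, 1.70, 1.70, 2.05, 2.05, 1.70, 1.70, 1.85, 2.35),
    charge = c(0, 0, 0, 0, -1, 0, 1, -1, 0),
    mass = c(36, 0, 36, 54, 54, 36, 36, 35.5, 72),
    # excess electrons over water (0.334 e/A^3) for the bead volume
    xray_contrast = c(19.2, 19.2, 16.5, 6.1, 37.4, 18.0, 7.3, 9.2, 0),
    # excess neutron scattering length over light water, fm
    neutron_contrast = c(22.0, 22.0, 18.5, 8.3, 28.6, 20.4, 3.6, 9.0, 0)
  )
}

# lookup helper: row of the bead table for a given type name
bead_row <- function(type, table = bead_types()) {
  i <- match(type, table$name)
  if (anyNA(i)) abort(paste0("unknown bead type: ",
                             paste(type[is.na(i)], collapse = ", ")))
  table[i, ]
}
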