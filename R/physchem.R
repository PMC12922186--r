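#' Solution specification
#'
#' Bundles the bookkeeping quantities of a solution-phase simulation box:
#' how many solute molecules sit in a cubic periodic box of a given side, at
#' which temperature, in a solvent of which viscosity.  Used by
#' [molar_concentration()] and [stokes_einstein_radius()].
#'
#' @param n_molecules Number of solute molecules in the box (>= 0).
#' @param box_side Cubic box side in nm (> 0).
#' @param temperature Temperature in K (> 0). Default 298.15 K.
#' @param viscosity Dynamic solvent viscosity in Pa s (> 0). Default is water
#'   at 25 C, 8.91e-4 Pa s.
#'
#' @return A one-row tibble of class `solution_spec`.
#' @examples
#' solution_spec(41, 14)
#' @export
solution_spec <- function(n_molecules, box_side, temperature = 298.15,
                          viscosity = 8.91e-4) {
  if (n_molecules < 0) abort("`n_molecules` must be >= 0.")
  if (box_side <= 0) abort("`box_side` must be > 0 (nm).")
  if (temperature <= 0) abort("`temperature` must be > 0 (K).")
  if (viscosity <= 0) abort("`viscosity` must be > 0 (Pa s).")
  out <- tibble(
    n_molecules = as.numeric(n_molecules), box_side = as.numeric(box_side),
    temperature = as.numeric(temperature), viscosity = as.numeric(viscosity)
  )
  class(out) <- c("solution_spec", class(out))
  out
}

#' Molar concentration of a cubic simulation box
#'
#' Computes `n / (N_A * L^3)` in millimolar for `n` molecules in a cubic box
#' of side `L` nm.  Exact inverse of [box_side_for_concentration()].
#'
#' @param spec A [solution_spec()], or a molecule count if `box_side` given.
#' @param box_side Optional cubic box side in nm, used when `spec` is a bare
#'   molecule count.
#'
#' @return Concentration in mM.
#' @examples
#' molar_concentration(solution_spec(41, 14))  # ~ 24.8 mM
#' @export
molar_concentration <- function(spec, box_side = NULL) {
  if (inherits(spec, "solution_spec")) {
    n <- spec$n_molecules
    L <- spec$box_side
  } else {
    n <- spec
    L <- box_side
  }
  if (is.null(L) || any(L <= 0)) abort("box side must be > 0 (nm).")
  if (any(n < 0)) abort("molecule count must be >= 0.")
  # L^3 in litres: (L * 1e-8 dm)^3
  vol_litre <- (L * 1e-8)^3
  n / .const$N_A / vol_litre * 1e3
}

#' Box side giving a target concentration
#'
#' Inverse of [molar_concentration()]: the cubic box side (nm) that holds `n`
#' molecules at concentration `c` mM.
#'
#' @param n_molecules Molecule count (> 0).
#' @param concentration Target concentration in mM (> 0).
#' @return Box side in nm.
#' @examples
#' box_side_for_concentration(41, 25)
#' @export
box_side_for_concentration <- function(n_molecules, concentration) {
  if (n_molecules <= 0) abort("`n_molecules` must be > 0.")
  if (concentration <= 0) abort("`concentration` must be > 0 (mM).")
  vol_litre <- n_molecules / .const$N_A / (concentration / 1e3)
  vol_litre^(1 / 3) * 1e8
}

#' Bragg-type conversion between a repeat distance and q
#'
#' The `q = 2 pi / d` relation linking a real-space repeat (e.g. the
#' face-to-face aromatic stacking distance, ~3.4 A) to the scattering-vector
#' position of the corresponding intensity feature.  The function is an
#' involution: applying it twice returns the input, so it converts in both
#' directions (d in A gives q in 1/A and vice versa).
#'
#' @param d Repeat distance in A (or a q value in 1/A to invert).
#' @return `2 * pi / d`.
#' @examples
#' bragg_q(3.4)  # ~ 1.85 1/A, the pi-stacking upturn position
#' @export
bragg_q <- function(d) {
  if (any(d <= 0)) abort("distance (or q) must be > 0.")
  2 * pi / d
}

#' Scattering vector from scattering angle
#'
#' `q = 4 pi sin(theta / 2) / lambda` for scattering angle `theta` (radians)
#' and wavelength `lambda` (A).
#'
#' @param theta Scattering angle in radians, `0 <= theta < pi`.
#' @param lambda Wavelength in A (> 0).
#' @return q in 1/A; strictly increasing in `theta`.
#' @examples
#' q_from_angle(pi / 3, 1)  # sin(30 deg) = 0.5 -> 2 pi
#' @export
q_from_angle <- function(theta, lambda) {
  if (any(lambda <= 0)) abort("`lambda` must be > 0 (A).")
  if (any(theta < 0 | theta >= pi)) abort("`theta` must be in [0, pi).")
  4 * pi * sin(theta / 2) / lambda
}

#' Stokes-Einstein hydrodynamic radius
#'
#' `R_h = k_B T / (6 pi eta D)`, converting a translational diffusion
#' coefficient (e.g. from DOSY NMR) into a hydrodynamic radius.
#'
#' @param diffusion Diffusion coefficient in m^2/s (> 0).
#' @param spec A [solution_spec()] carrying temperature (K) and viscosity
#'   (Pa s); defaults to water at 298.15 K.
#' @return Hydrodynamic radius in nm.
#' @examples
#' stokes_einstein_radius(1.63e-10)  # ~ 1.5 nm
#' @export
stokes_einstein_radius <- function(diffusion, spec = solution_spec(0, 1)) {
  if (any(diffusion <= 0)) abort("`diffusion` must be > 0 (m^2/s).")
  r_m <- .const$k_B * spec$temperature / (6 * pi * spec$viscosity * diffusion)
  r_m * 1e9
}
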