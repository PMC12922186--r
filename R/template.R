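#' Build a triskelion amphiphile template
#'
#' Constructs the bead-level geometry of one coarse-grained triskelion
#' amphiphile: a rigid planar aromatic core of three real beads (an
#' equilateral triangle) plus three massless virtual sites fixed by affine
#' rules over the real core beads, three hydrophilic arms
#' (linker-alkyl-sulfonate, terminating in a -1 sulfonate bead) and three
#' hydrophobic single-bead phenyl arms, alternating around the core.
#'
#' Arms are given a small azimuthal skew and out-of-plane lift, which makes
#' the molecule chiral: its two faces are distinguishable, the feature that
#' drives up-down alternation in stacks.  `face_normal` (the +z axis of the
#' local frame) labels the "up" face.
#'
#' @param arm_hydrophilic Radial extent of the hydrophilic arms beyond the
#'   core edge, A. Default 7.
#' @param arm_hydrophobic Radial extent of the hydrophobic phenyl bead beyond
#'   the core edge, A. Default 6.
#' @param core_edge Edge length of the rigid core triangle, A. Default 5.
#' @param skew Azimuthal skew per arm bead, degrees; nonzero values make the
#'   template chiral. Default 10.
#' @param bead_table Bead-type table, see [bead_types()].
#'
#' @return An object of class `cg_template`: a list with elements `sites`
#'   (tibble: `site`, `name`, `type`, `role`, `x`, `y`, `z`, `virtual`,
#'   `radius`, `charge`, `mass`, `xray_contrast`, `neutron_contrast`),
#'   `virtual_rules`, `bonds`, `angles`, `dihedrals`, `face_normal`.
#' @examples
#' tpl <- build_template()
#' sum(tpl$sites$charge)  # -3
#' @export
build_template <- function(arm_hydrophilic = 7, arm_hydrophobic = 6,
                           core_edge = 5, skew = 10,
                           bead_table = bead_types()) {
  if (arm_hydrophilic <= 0 || arm_hydrophobic <= 0 || core_edge <= 0) {
    abort("template lengths must be positive (A).")
  }
  rc <- core_edge / sqrt(3)  # circumradius of the core triangle
  ang_core <- deg2rad(c(90, 210, 330))
  core <- cbind(rc * cos(ang_core), rc * sin(ang_core), 0)

  # virtual site k sits opposite real core bead k at the same radius:
  # v_k = (2 c_i + 2 c_j - c_k) / 3, an affine combination (coefs sum to 1)
  vrule <- list(
    list(site = 4L, ref = c(2L, 3L, 1L), coef = c(2, 2, -1) / 3),
    list(site = 5L, ref = c(1L, 3L, 2L), coef = c(2, 2, -1) / 3),
    list(site = 6L, ref = c(1L, 2L, 3L), coef = c(2, 2, -1) / 3)
  )
  virt <- t(vapply(vrule, function(r) {
    colSums(core[r$ref, , drop = FALSE] * r$coef)
  }, numeric(3)))

  sk <- deg2rad(skew)
  arm_site <- function(base_angle, radial, dskew, z) {
    a <- base_angle + dskew
    c(radial * cos(a), radial * sin(a), z)
  }
  # hydrophilic arms off the real core directions
  philic <- list()
  for (k in 1:3) {
    off <- rc + c(2.3, 4.6, 7.0) * (arm_hydrophilic / 7)
    philic[[k]] <- rbind(
      arm_site(ang_core[k], off[1], sk, 0.5),
      arm_site(ang_core[k], off[2], 2 * sk, 1.0),
      arm_site(ang_core[k], off[3], 3 * sk, 1.5)
    )
  }
  # hydrophobic phenyl bead off each virtual-site direction
  ang_virt <- ang_core + pi
  phobic <- t(vapply(1:3, function(k) {
    arm_site(ang_virt[k], rc + arm_hydrophobic, sk, -0.8)
  }, numeric(3)))

  coords <- rbind(core, virt, do.call(rbind, philic), phobic)
  types <- c(rep("TC5e", 3), rep("TC5v", 3),
             rep(c("TN2a", "SC1", "SQ4n"), 3), rep("TC5", 3))
  names_ <- c(paste0("C", 1:3), paste0("V", 1:3),
              as.vector(vapply(1:3, function(k) paste0(c("L", "A", "S"), k),
                               character(3))),
              paste0("P", 1:3))
  info <- bead_row(types, bead_table)
  sites <- tibble(
    site = seq_len(nrow(coords)), name = names_, type = types,
    role = info$role, x = coords[, 1], y = coords[, 2], z = coords[, 3],
    virtual = info$role == "core-virtual",
    radius = info$radius, charge = info$charge, mass = info$mass,
    xray_contrast = info$xray_contrast,
    neutron_contrast = info$neutron_contrast
  )

  arm_base <- function(k) 6L + 3L * (k - 1L)  # first hydrophilic bead of arm k
  bonds <- c(
    list(c(1L, 2L), c(2L, 3L), c(1L, 3L)),
    purrr::map(1:3, ~ c(.x, arm_base(.x) + 1L)),
    purrr::map(1:3, ~ c(arm_base(.x) + 1L, arm_base(.x) + 2L)),
    purrr::map(1:3, ~ c(arm_base(.x) + 2L, arm_base(.x) + 3L)),
    purrr::map(1:3, ~ c(.x + 3L, 15L + .x))
  )
  angles <- c(
    purrr::map(1:3, ~ c(.x, arm_base(.x) + 1L, arm_base(.x) + 2L)),
    purrr::map(1:3, ~ c(arm_base(.x) + 1L, arm_base(.x) + 2L,
                        arm_base(.x) + 3L))
  )
  core_others <- list(c(2L, 3L), c(3L, 1L), c(1L, 2L))
  dihedrals <- c(
    # sulfonate-tail dihedral: core_j - core_k - linker_k - alkyl_k
    purrr::map(1:3, ~ c(core_others[[.x]][1], .x,
                        arm_base(.x) + 1L, arm_base(.x) + 2L)),
    # phenyl dihedral: core_i - core_j - virtual_k - phenyl_k
    purrr::map(1:3, ~ c(core_others[[.x]][1], core_others[[.x]][2],
                        .x + 3L, 15L + .x))
  )

  structure(
    list(sites = sites, virtual_rules = vrule, bonds = bonds,
         angles = angles, dihedrals = dihedrals,
         face_normal = c(0, 0, 1)),
    class = "cg_template"
  )
}

#' @export
print.cg_template <- function(x, ...) {
  cat("<cg_template> ", nrow(x$sites), " sites (",
      sum(!x$sites$virtual), " real, ", sum(x$sites$virtual),
      " virtual), net charge ", sum(x$sites$charge), "\n", sep = "")
  invisible(x)
}

# coordinates matrix of a template (n x 3)
template_coords <- function(template) {
  as.matrix(template$sites[, c("x", "y", "z")])
}

# recompute virtual-site positions from the rules; coords n x 3 for one molecule
apply_virtual_rules <- function(coords, rules) {
  for (r in rules) {
    coords[r$site, ] <- colSums(coords[r$ref, , drop = FALSE] * r$coef)
  }
  coords
}

# largest deviation (A) of virtual sites from their affine rules
virtual_site_residual <- function(coords, rules) {
  res <- 0
  for (r in rules) {
    want <- colSums(coords[r$ref, , drop = FALSE] * r$coef)
    res <- max(res, sqrt(sum((coords[r$site, ] - want)^2)))
  }
  res
}
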