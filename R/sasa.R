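# deterministic Fibonacci sphere lattice: n nearly uniform unit vectors
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z * z))
  phi <- i * pi * (3 - sqrt(5))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Point-sampling SASA: each bead's accessible sphere (radius + probe) is
#' covered with a deterministic Fibonacci lattice of `n_sphere_points`
#' points; a point is accessible if it lies outside every neighbouring
#' bead's accessible sphere (minimum-image distances).  Deterministic for a
#' fixed point count — no RNG.  Counterions, solvent and virtual sites are
#' excluded by default.
#'
#' @param config A [cg_configuration()].
#' @param probe_radius Probe radius in A (>= 0). Default 1.4.
#' @param n_sphere_points Lattice points per bead. Default 960.
#' @param include_roles Bead roles entering the calculation.
#' @return Tibble of per-molecule areas (`molecule`, `area` in A^2) with
#'   attribute `total` (sum, A^2).
#' @examples
#' ens <- build_ensemble(ensemble_recipe(n_molecules = 4, seed = 4),
#'                       build_template())
#' s <- sasa(ens$configurations[[1]])
#' attr(s, "total")
#' @export
sasa <- function(config, probe_radius = 1.4, n_sphere_points = 960,
                 include_roles = c("core", "linker", "alkyl", "sulfonate",
                                   "phenyl")) {
  if (probe_radius < 0) abort("`probe_radius` must be >= 0 (A).")
  b <- config$beads[!config$beads$virtual &
                      config$beads$role %in% include_roles, ]
  if (!nrow(b)) abort("no beads selected for SASA.")
  if (anyNA(b$radius) || any(b$radius <= 0)) {
    bad <- unique(b$type[is.na(b$radius) | b$radius <= 0])
    abort(paste("missing/invalid radius for bead type:",
                paste(bad, collapse = ", ")))
  }
  xyz <- as.matrix(b[, c("x", "y", "z")])
  rad <- b$radius + probe_radius
  n <- nrow(b)
  pts <- fibonacci_sphere(n_sphere_points)
  area <- numeric(n)
  # neighbour cut: beads further than r_i + max(r_j) cannot bury any point
  d_all <- min_image_dist(xyz, xyz, config$box)
  for (i in seq_len(n)) {
    nb <- which(d_all[i, ] < rad[i] + rad & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * rad[i]^2
      next
    }
    p <- sweep(pts * rad[i], 2, xyz[i, ], `+`)
    # minimum-image displacement from each test point to each neighbour
    acc <- rep(TRUE, n_sphere_points)
    for (j in nb) {
      dx <- sweep(p, 2, xyz[j, ], `-`)
      dx <- min_image(dx, config$box)
      acc <- acc & rowSums(dx * dx) > rad[j]^2
      if (!any(acc)) break
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_sphere_points
  }
  out <- dplyr::summarise(
    dplyr::group_by(tibble(molecule = b$molecule, a = area),
                    .data$molecule),
    area = sum(.data$a), .groups = "drop"
  )
  attr(out, "total") <- sum(area)
  out
}
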