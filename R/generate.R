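#' Stack specification
#'
#' Parameters of one face-to-face pi-stack of triskelion molecules.
#'
#' @param n_units Number of stacked molecules (>= 1).
#' @param d_stack Inter-core spacing in A (> 0).  Default 4.5 A, between the
#'   atomistic pi-stacking repeat (~3.4 A) and the coarse-grained
#'   centre-of-mass stacking peak (~6.5 A): coarse beads are fatter than
#'   atoms.
#' @param alternate_faces Flip every second molecule so chiral faces
#'   alternate up-down-up-down. Default `TRUE`.
#' @param twist_per_unit Azimuthal twist per stacked unit, degrees.
#' @param jitter_sigma Gaussian positional jitter per molecule, A (>= 0).
#' @return A list of class `stack_spec`.
#' @export
stack_spec <- function(n_units, d_stack = 4.5, alternate_faces = TRUE,
                       twist_per_unit = 0, jitter_sigma = 0) {
  if (n_units < 1) abort("`n_units` must be >= 1.")
  if (d_stack <= 0) abort("`d_stack` must be > 0 (A).")
  if (jitter_sigma < 0) abort("`jitter_sigma` must be >= 0 (A).")
  structure(list(n_units = as.integer(n_units), d_stack = d_stack,
                 alternate_faces = alternate_faces,
                 twist_per_unit = twist_per_unit,
                 jitter_sigma = jitter_sigma),
            class = "stack_spec")
}

# beads tibble for one posed molecule (coords already transformed)
mol_beads <- function(template, coords, molecule) {
  s <- template$sites
  tibble(
    molecule = molecule, site = s$site, name = s$name, type = s$type,
    role = s$role, x = coords[, 1], y = coords[, 2], z = coords[, 3],
    virtual = s$virtual, radius = s$radius, charge = s$charge,
    mass = s$mass, xray_contrast = s$xray_contrast,
    neutron_contrast = s$neutron_contrast
  )
}

# hard-core overlap criterion: closer than factor * (r_i + r_j)
HARD_CORE_FACTOR <- 0.7

# beads tibble for a stack fragment at the origin (units along +z); internal
stack_fragment <- function(template, spec, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- template_coords(template)
  frags <- vector("list", spec$n_units)
  for (k in seq_len(spec$n_units)) {
    rot <- rot_z(deg2rad(spec$twist_per_unit * (k - 1)))
    # flipped units are also rotated by 60 degrees about the stack axis so
    # the six arms interdigitate instead of clashing tip-to-tip
    if (spec$alternate_faces && k %% 2 == 0) {
      rot <- rot %*% rot_z(pi / 3) %*% rot_x(pi)
    }
    shift <- c(0, 0, spec$d_stack * (k - 1))
    if (spec$jitter_sigma > 0) shift <- shift + rnorm(3, 0, spec$jitter_sigma)
    xyz <- rigid_transform(base, rot, shift)
    xyz <- apply_virtual_rules(xyz, template$virtual_rules)
    frags[[k]] <- mol_beads(template, xyz, k)
  }
  out <- dplyr::bind_rows(frags)
  check_stack_overlap(out, template)
  out
}

check_stack_overlap <- function(beads, template) {
  real <- beads[!beads$virtual, ]
  for (k in unique(real$molecule)) {
    a <- real[real$molecule == k, ]
    b <- real[real$molecule > k, ]
    if (!nrow(b)) next
    d <- min_image_dist(as.matrix(a[, c("x", "y", "z")]),
                        as.matrix(b[, c("x", "y", "z")]))
    lim <- HARD_CORE_FACTOR * outer(a$radius, b$radius, `+`)
    bad <- which(d < lim, arr.ind = TRUE)
    if (nrow(bad)) {
      abort(sprintf(
        "hard-core overlap in stack: molecule %d bead %s vs molecule %d bead %s (%.2f A)",
        k, a$name[bad[1, 1]], b$molecule[bad[1, 2]], b$name[bad[1, 2]],
        d[bad[1, 1], bad[1, 2]]))
    }
  }
  invisible(beads)
}

#' Place a face-alternating pi-stack
#'
#' Builds a stack of `spec$n_units` copies of `template`, consecutive core
#' centroids separated by `d_stack` (plus optional Gaussian jitter), every
#' second molecule flipped by a 180-degree rotation about an in-plane axis
#' when `alternate_faces` is set (which anti-aligns consecutive face
#' normals while preserving chirality), then posed rigidly.
#'
#' @param template A [build_template()] object.
#' @param spec A [stack_spec()].
#' @param rotation 3x3 rotation applied to the whole stack.
#' @param translation Length-3 translation (A) applied after rotation.
#' @param box Box edge(s) in A for the returned configuration; default
#'   encloses the fragment with a 20 A margin.
#' @param seed Optional RNG seed for the jitter.
#' @return A [cg_configuration()] holding the stack.
#' @examples
#' st <- place_stack(build_template(), stack_spec(4))
#' @export
place_stack <- function(template, spec, rotation = diag(3),
                        translation = c(0, 0, 0), box = NULL, seed = NULL) {
  beads <- stack_fragment(template, spec, seed)
  xyz <- rigid_transform(as.matrix(beads[, c("x", "y", "z")]),
                         rotation, translation)
  beads$x <- xyz[, 1]; beads$y <- xyz[, 2]; beads$z <- xyz[, 3]
  if (is.null(box)) {
    ext <- apply(xyz, 2, function(v) diff(range(v)))
    box <- max(ext) + 40
    xyz0 <- sweep(xyz, 2, apply(xyz, 2, min) - 20, `-`)
    beads$x <- xyz0[, 1]; beads$y <- xyz0[, 2]; beads$z <- xyz0[, 3]
  }
  cg_configuration(beads, box, template)
}

#' Ensemble recipe
#'
#' Declares the composition of a synthetic ensemble: how many molecules, in
#' which box, which fraction dissolved as monomers, how the remainder is
#' split over aggregates of given sizes and shapes.  Defaults emulate the
#' dilute aqueous condition: 41 molecules at 25 mM (14 nm box), ~20%
#' dissolved, the rest in short face-alternating stacks of 2-8 molecules
#' dominated by sizes <= 4.
#'
#' @param n_molecules Total amphiphile count. Default 41.
#' @param box_side Cubic box side in nm. Default the side that gives 25 mM
#'   for `n_molecules`.
#' @param monomer_fraction Expected fraction of dissolved monomers in
#'   `[0, 1]`. Default 0.2.
#' @param stack_size_weights Named numeric: aggregate size -> weight.
#'   Default decreasing weights over sizes 2-8.
#' @param aggregate_shapes Named weights over `stack`, `prolate-cylinder`,
#'   `oblate-disc`. Default all stacks.
#' @param salt_pairs Number of extra Na+/Cl- pairs to scatter in the box.
#' @param d_stack,jitter_sigma,twist_per_unit Stack geometry, see
#'   [stack_spec()].
#' @param min_separation Minimum bead-bead distance between independently
#'   placed fragments, A. Keeps distinct aggregates resolvable by the
#'   default 6 A clustering cutoff. Default 7.
#' @param seed Default RNG seed used by [build_ensemble()].
#' @return A list of class `ensemble_recipe`.
#' @export
ensemble_recipe <- function(n_molecules = 41,
                            box_side = box_side_for_concentration(n_molecules, 25),
                            monomer_fraction = 0.2,
                            stack_size_weights = c(`2` = 0.30, `3` = 0.25,
                                                   `4` = 0.25, `5` = 0.10,
                                                   `6` = 0.06, `7` = 0.03,
                                                   `8` = 0.01),
                            aggregate_shapes = c(stack = 1,
                                                 `prolate-cylinder` = 0,
                                                 `oblate-disc` = 0),
                            salt_pairs = 0, d_stack = 4.5,
                            jitter_sigma = 0.3, twist_per_unit = 0,
                            min_separation = 7, seed = 1L) {
  if (n_molecules < 1) abort("`n_molecules` must be >= 1.")
  if (box_side <= 0) abort("`box_side` must be > 0 (nm).")
  if (monomer_fraction < 0 || monomer_fraction > 1) {
    abort("`monomer_fraction` must be in [0, 1].")
  }
  if (any(stack_size_weights < 0) || any(aggregate_shapes < 0)) {
    abort("weights must be nonnegative.")
  }
  if (monomer_fraction < 1 && sum(stack_size_weights) <= 0) {
    abort("stack_size_weights must have positive sum.")
  }
  structure(list(
    n_molecules = as.integer(n_molecules), box_side = box_side,
    monomer_fraction = monomer_fraction,
    stack_size_weights = stack_size_weights,
    aggregate_shapes = aggregate_shapes / sum(aggregate_shapes),
    salt_pairs = as.integer(salt_pairs), d_stack = d_stack,
    jitter_sigma = jitter_sigma, twist_per_unit = twist_per_unit,
    min_separation = min_separation, seed = as.integer(seed)
  ), class = "ensemble_recipe")
}

# sample the fragment composition (sizes + shapes) for one configuration
sample_composition <- function(recipe) {
  n <- recipe$n_molecules
  n_mono <- rbinom(1, n, recipe$monomer_fraction)
  sizes <- integer(0)
  left <- n - n_mono
  w <- recipe$stack_size_weights
  sz <- as.integer(names(w))
  while (left > 0) {
    s <- if (left == 1) 1L else if (length(sz) == 1) sz else
      sample(sz, 1, prob = w)
    s <- min(s, left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  shapes <- character(length(sizes))
  shp <- names(recipe$aggregate_shapes)
  for (i in seq_along(sizes)) {
    shapes[i] <- if (sizes[i] <= 2 || length(shp) == 1) shp[
      if (sizes[i] <= 2) match("stack", shp, nomatch = 1L) else 1L] else
      sample(shp, 1, prob = recipe$aggregate_shapes)
  }
  list(n_monomers = n_mono, sizes = sizes, shapes = shapes)
}

# beads tibble for one fragment at the origin
make_fragment <- function(template, size, shape, recipe) {
  if (size == 1) {
    xyz <- template_coords(template)
    return(mol_beads(template, xyz, 1L))
  }
  if (shape == "stack") {
    return(stack_fragment(template, stack_spec(
      size, recipe$d_stack, TRUE, recipe$twist_per_unit,
      recipe$jitter_sigma)))
  }
  if (shape == "prolate-cylinder") {
    # a sloppy column: larger jitter, random twist per unit
    return(stack_fragment(template, stack_spec(
      size, recipe$d_stack, TRUE,
      twist_per_unit = runif(1, 10, 50),
      jitter_sigma = max(recipe$jitter_sigma, 1.2))))
  }
  if (shape == "oblate-disc") {
    # two layers of a sunflower-spiral patch in the xy plane
    per_layer <- ceiling(size / 2)
    a <- 13
    frags <- vector("list", size)
    for (k in seq_len(size)) {
      layer <- (k - 1) %/% per_layer
      j <- (k - 1) %% per_layer
      r <- a * sqrt(j)
      th <- j * 2.39996323  # golden angle
      rot <- rot_z(runif(1, 0, 2 * pi))
      if (layer == 1) rot <- rot %*% rot_x(pi)
      shift <- c(r * cos(th), r * sin(th), layer * recipe$d_stack) +
        rnorm(3, 0, recipe$jitter_sigma)
      xyz <- rigid_transform(template_coords(template), rot, shift)
      xyz <- apply_virtual_rules(xyz, template$virtual_rules)
      frags[[k]] <- mol_beads(template, xyz, k)
    }
    return(dplyr::bind_rows(frags))
  }
  abort(paste("unknown aggregate shape:", shape))
}

#' Build a synthetic ensemble
#'
#' Realizes an [ensemble_recipe()]: samples a fragment composition
#' (binomial monomer count, aggregate sizes from the size weights), builds
#' each fragment and inserts it into the periodic box at a random pose by
#' sequential random insertion with rejection (no energies).  Molecules are
#' stored whole (unwrapped); wrapping happens at file-write time.  The
#' result is a pure function of `(recipe, seed)`.
#'
#' @param recipe An [ensemble_recipe()].
#' @param template A [build_template()] object.
#' @param n_configurations Number of independent snapshots. Default 1.
#' @param seed RNG seed; defaults to `recipe$seed`.
#' @param max_attempts Insertion attempts per fragment before failing.
#' @return A [cg_ensemble()] of `n_configurations` snapshots.
#' @examples
#' ens <- build_ensemble(ensemble_recipe(n_molecules = 8, seed = 7),
#'                       build_template())
#' @export
build_ensemble <- function(recipe, template, n_configurations = 1,
                           seed = recipe$seed, max_attempts = 500) {
  configs <- vector("list", n_configurations)
  for (i in seq_len(n_configurations)) {
    set.seed(derive_seed(seed, i))
    configs[[i]] <- build_configuration(recipe, template, max_attempts)
  }
  cg_ensemble(configs)
}

derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 1e6) * 2048 + 7919 * i) %% 2147483647L
}

build_configuration <- function(recipe, template, max_attempts = 500) {
  box <- rep(recipe$box_side * A_PER_NM, 3)
  comp <- sample_composition(recipe)
  sizes <- c(rep(1L, comp$n_monomers), comp$sizes)
  shapes <- c(rep("monomer", comp$n_monomers), comp$shapes)
  placed <- list()
  placed_xyz <- NULL
  placed_rad <- NULL
  next_mol <- 1L
  for (f in seq_along(sizes)) {
    # rejection sampling: re-draw the fragment's internal jitter if it
    # produced a hard-core clash
    frag <- NULL
    for (try in seq_len(50)) {
      frag <- tryCatch(make_fragment(template, sizes[f], shapes[f], recipe),
                       error = function(e) {
                         if (grepl("hard-core overlap", conditionMessage(e)))
                           NULL else stop(e)
                       })
      if (!is.null(frag)) break
    }
    if (is.null(frag)) {
      abort(sprintf(
        "packing failure: fragment %d (size %d, %s) always self-overlaps",
        f, sizes[f], shapes[f]))
    }
    fx <- as.matrix(frag[, c("x", "y", "z")])
    fx <- sweep(fx, 2, colMeans(fx))  # centre the fragment
    ok <- FALSE
    for (try in seq_len(max_attempts)) {
      rot <- random_rotation()
      pos <- runif(3) * box
      xyz <- rigid_transform(fx, rot, pos)
      if (is.null(placed_xyz)) { ok <- TRUE; break }
      real <- !frag$virtual
      d <- min_image_dist(xyz[real, , drop = FALSE], placed_xyz, box)
      if (min(d) >= recipe$min_separation) { ok <- TRUE; break }
    }
    if (!ok) {
      abort(sprintf(
        "packing failure: could not place fragment %d (size %d, %s) after %d attempts",
        f, sizes[f], shapes[f], max_attempts))
    }
    frag$x <- xyz[, 1]; frag$y <- xyz[, 2]; frag$z <- xyz[, 3]
    frag$molecule <- frag$molecule + next_mol - 1L
    next_mol <- next_mol + sizes[f]
    real <- !frag$virtual
    placed_xyz <- rbind(placed_xyz, xyz[real, , drop = FALSE])
    placed_rad <- c(placed_rad, frag$radius[real])
    placed[[f]] <- frag
  }
  config <- cg_configuration(dplyr::bind_rows(placed), box, template)
  if (recipe$salt_pairs > 0) {
    config <- add_ions(config, rep(c("TQ5", "CL"), recipe$salt_pairs))
  }
  config
}

# scatter free ions of the given types into the box (rejection sampling,
# hard-core exclusion only)
add_ions <- function(config, types, max_attempts = 500) {
  if (!length(types)) return(config)
  info <- bead_row(types)
  box <- config$box
  real <- !config$beads$virtual
  xyz_all <- config_coords(config)[real, , drop = FALSE]
  rad_all <- config$beads$radius[real]
  next_mol <- max(config$beads$molecule) + 1L
  rows <- vector("list", length(types))
  for (k in seq_along(types)) {
    ok <- FALSE
    for (try in seq_len(max_attempts)) {
      pos <- matrix(runif(3) * box, 1, 3)
      d <- min_image_dist(pos, xyz_all, box)
      lim <- HARD_CORE_FACTOR * (info$radius[k] + rad_all)
      if (all(d >= lim)) { ok <- TRUE; break }
    }
    if (!ok) abort("box too dense to place ions.")
    rows[[k]] <- tibble(
      molecule = next_mol, site = 1L, name = info$name[k],
      type = info$name[k], role = info$role[k],
      x = pos[1], y = pos[2], z = pos[3], virtual = FALSE,
      radius = info$radius[k], charge = info$charge[k], mass = info$mass[k],
      xray_contrast = info$xray_contrast[k],
      neutron_contrast = info$neutron_contrast[k]
    )
    xyz_all <- rbind(xyz_all, pos)
    rad_all <- c(rad_all, info$radius[k])
    next_mol <- next_mol + 1L
  }
  config$beads <- dplyr::bind_rows(config$beads, rows)
  config
}

#' Add neutralizing counterions
#'
#' Adds exactly enough monovalent counterions (Na+ for a net-negative box,
#' Cl- for net-positive) to make the total charge exactly zero, placed
#' uniformly at random outside the hard-core exclusion of existing beads.
#'
#' @param config A [cg_configuration()].
#' @param seed Optional RNG seed.
#' @param max_attempts Placement attempts per ion.
#' @return The configuration with ions appended (each its own molecule).
#' @examples
#' ens <- build_ensemble(ensemble_recipe(n_molecules = 4, seed = 3),
#'                       build_template())
#' neutral <- add_counterions(ens$configurations[[1]])
#' sum(neutral$beads$charge)  # 0
#' @export
add_counterions <- function(config, seed = NULL, max_attempts = 500) {
  if (!is.null(seed)) set.seed(seed)
  net <- sum(config$beads$charge)
  if (net == 0) return(config)
  n <- abs(net)
  type <- if (net < 0) "TQ5" else "CL"
  add_ions(config, rep(type, n), max_attempts = max_attempts)
}

#' Face normals of molecules in a configuration
#'
#' Estimated from the rigid core triangle: the unit normal of the plane
#' through the three real core beads, oriented by the template's bead
#' ordering (counter-clockwise seen from the "up" face), so the sign tracks
#' which chiral face points where.
#'
#' @param config A [cg_configuration()].
#' @return Tibble `molecule`, `nx`, `ny`, `nz`.
#' @export
molecule_face_normals <- function(config) {
  b <- dplyr::filter(config$beads, .data$role == "core")
  purrr::map_dfr(split(b, b$molecule), function(m) {
    m <- m[order(m$site), ]
    u <- c(m$x[2] - m$x[1], m$y[2] - m$y[1], m$z[2] - m$z[1])
    v <- c(m$x[3] - m$x[1], m$y[3] - m$y[1], m$z[3] - m$z[1])
    n <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
    n <- n / sqrt(sum(n^2))
    tibble(molecule = m$molecule[1], nx = n[1], ny = n[2], nz = n[3])
  })
}
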