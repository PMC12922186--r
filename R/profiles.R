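#' Centre-of-mass pair radial distribution function
#'
#' Shell-normalized g(r) over molecular centres of mass with minimum-image
#' periodic distances, averaged over the ensemble with its weights.
#'
#' @param ensemble A [cg_ensemble()] (or a single configuration).
#' @param r_max Histogram range in A; must not exceed half the shortest box
#'   edge. Default half box.
#' @param bin_width Bin width in A (> 0). Default 0.5.
#' @return Tibble of class `radial_profile`: `r` (bin centre, A), `g`,
#'   `count` (mean pair count per configuration).
#' @export
com_pair_rdf <- function(ensemble, r_max = NULL, bin_width = 0.5) {
  ens <- as_ensemble(ensemble)
  if (bin_width <= 0) abort("`bin_width` must be > 0 (A).")
  half <- min(purrr::map_dbl(ens$configurations, ~ min(.x$box))) / 2
  if (is.null(r_max)) r_max <- half
  if (r_max > half + 1e-9) {
    abort("`r_max` exceeds half the shortest box edge.")
  }
  breaks <- seq(0, r_max, by = bin_width)
  if (tail(breaks, 1) < r_max) breaks <- c(breaks, r_max)
  mids <- head(breaks, -1) + diff(breaks) / 2
  g_acc <- numeric(length(mids))
  c_acc <- numeric(length(mids))
  for (i in seq_along(ens$configurations)) {
    cfg <- ens$configurations[[i]]
    w <- ens$weights[i]
    com <- as.matrix(molecule_com(cfg)[, c("x", "y", "z")])
    n <- nrow(com)
    if (n < 2) next
    d <- min_image_dist(com, com, cfg$box)
    d <- d[upper.tri(d)]
    counts <- graphics::hist(d[d < r_max], breaks = breaks,
                             plot = FALSE)$counts
    vol <- prod(cfg$box)
    shell <- 4 / 3 * pi * (breaks[-1]^3 - head(breaks, -1)^3)
    # ideal-gas pair count in each shell
    ideal <- n * (n - 1) / 2 * shell / vol
    g_acc <- g_acc + w * counts / ideal
    c_acc <- c_acc + w * counts
  }
  out <- tibble(r = mids, g = g_acc, count = c_acc)
  class(out) <- c("radial_profile", class(out))
  out
}

# resolve a bead selection to row indices of config$beads
select_beads <- function(config, selection) {
  b <- config$beads
  if (is.logical(selection)) return(which(selection))
  if (is.numeric(selection)) return(as.integer(selection))
  if (is.character(selection)) {
    return(which(b$name %in% selection | b$type %in% selection |
                   b$role %in% selection))
  }
  abort("selection must be character (name/type/role), indices, or logical.")
}

#' Closest-approach distance series between two bead selections
#'
#' For each configuration, the minimum-image distance of the closest
#' (a, b) bead pair, e.g. between sulfonate tail beads of different
#' molecules as an aggregation order parameter.
#'
#' @param ensemble A [cg_ensemble()] or configuration.
#' @param selection_a,selection_b Bead selections: character vectors matched
#'   against bead `name`, `type` or `role`, bead row indices, or logical
#'   masks. `selection_b` defaults to `selection_a`.
#' @param exclude_same_molecule Drop intramolecular pairs. Default `TRUE`.
#' @return Tibble `frame`, `distance` (A).
#' @export
min_pair_distance_series <- function(ensemble, selection_a,
                                     selection_b = selection_a,
                                     exclude_same_molecule = TRUE) {
  ens <- as_ensemble(ensemble)
  purrr::imap_dfr(ens$configurations, function(cfg, i) {
    ia <- select_beads(cfg, selection_a)
    ib <- select_beads(cfg, selection_b)
    if (!length(ia) || !length(ib)) abort("empty bead selection.")
    d <- min_image_dist(config_coords(cfg, ia), config_coords(cfg, ib),
                        cfg$box)
    same_bead <- outer(ia, ib, `==`)
    d[same_bead] <- Inf
    if (exclude_same_molecule) {
      same_mol <- outer(cfg$beads$molecule[ia], cfg$beads$molecule[ib], `==`)
      d[same_mol] <- Inf
    }
    if (!any(is.finite(d))) abort("no admissible bead pairs in selection.")
    tibble(frame = i, distance = min(d))
  })
}

# bond angle (deg) at j for point triples; rows of p1, p2, p3
bond_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  dot <- rowSums(u * v)
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  atan2(sqrt(rowSums(cr * cr)), dot) * 180 / pi
}

# signed dihedral (deg, (-180, 180]) for point quadruples; NA when degenerate
dihedral_angle <- function(p1, p2, p3, p4, tol = 1e-10) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross_rows(b1, b2)
  n2 <- cross_rows(b2, b3)
  deg <- sqrt(rowSums(n1 * n1)) < tol | sqrt(rowSums(n2 * n2)) < tol
  b2n <- b2 / sqrt(rowSums(b2 * b2))
  x <- rowSums(n1 * n2)
  y <- rowSums(cross_rows(n1, n2) * b2n)
  phi <- atan2(y, x) * 180 / pi
  phi[phi <= -180] <- phi[phi <= -180] + 360
  phi[deg] <- NA_real_
  phi
}

cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Internal-coordinate histograms
#'
#' Normalized distributions of bond angles (over `[0, 180]` degrees) and
#' proper dihedrals (over `(-180, 180]`) for per-molecule site tuples, e.g.
#' the phenyl and sulfonate-tail dihedrals of the template, pooled over all
#' molecules and configurations.  Degenerate (collinear) dihedral frames
#' are excluded and counted.
#'
#' @param ensemble A [cg_ensemble()] or configuration.
#' @param angle_triples List of length-3 site-index vectors (template
#'   numbering); default the template's angle list.
#' @param dihedral_quadruples List of length-4 site-index vectors; default
#'   the template's dihedral list.
#' @param bin_width Bin width in degrees. Default 5.
#' @return Tibble `kind` ("angle"/"dihedral"), `tuple` (label), `bin_mid`
#'   (deg), `density` (per degree); attribute `n_excluded` counts dropped
#'   degenerate dihedrals.
#' @export
internal_coordinate_histograms <- function(ensemble, angle_triples = NULL,
                                           dihedral_quadruples = NULL,
                                           bin_width = 5) {
  ens <- as_ensemble(ensemble)
  tpl <- ens$configurations[[1]]$template
  if (is.null(angle_triples)) angle_triples <- tpl$angles
  if (is.null(dihedral_quadruples)) dihedral_quadruples <- tpl$dihedrals
  if (is.null(angle_triples) && is.null(dihedral_quadruples)) {
    abort("no angle or dihedral tuples given and no template available.")
  }

  site_xyz <- function(cfg, site) {
    b <- cfg$beads[!(cfg$beads$role %in% c("counterion", "solvent")), ]
    b <- b[b$site == site, ]
    as.matrix(b[order(b$molecule), c("x", "y", "z")])
  }

  n_excluded <- 0L
  rows <- list()
  hist_tbl <- function(vals, breaks, kind, tuple) {
    h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
    tibble(kind = kind, tuple = tuple,
           bin_mid = h$mids, density = h$density)
  }
  for (t in seq_along(angle_triples)) {
    tr <- angle_triples[[t]]
    vals <- unlist(purrr::map(ens$configurations, function(cfg) {
      bond_angle(site_xyz(cfg, tr[1]), site_xyz(cfg, tr[2]),
                 site_xyz(cfg, tr[3]))
    }))
    rows[[length(rows) + 1]] <- hist_tbl(
      vals, seq(0, 180, by = bin_width), "angle",
      paste(tr, collapse = "-"))
  }
  for (t in seq_along(dihedral_quadruples)) {
    qd <- dihedral_quadruples[[t]]
    vals <- unlist(purrr::map(ens$configurations, function(cfg) {
      dihedral_angle(site_xyz(cfg, qd[1]), site_xyz(cfg, qd[2]),
                     site_xyz(cfg, qd[3]), site_xyz(cfg, qd[4]))
    }))
    n_excluded <- n_excluded + sum(is.na(vals))
    vals <- vals[!is.na(vals)]
    rows[[length(rows) + 1]] <- hist_tbl(
      vals, seq(-180, 180, by = bin_width), "dihedral",
      paste(qd, collapse = "-"))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_excluded") <- n_excluded
  out
}
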