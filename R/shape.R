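#' Moment-of-inertia tensor of an aggregate
#'
#' Mass-weighted inertia tensor about the centre of mass,
#' `I = sum_i m_i (|r_i|^2 Id - r_i r_i^T)`, eigendecomposed with
#' eigenvalues sorted ascending and a right-handed eigenvector frame.
#' The aggregate must be whole (unwrapped): if any coordinate spread
#' exceeds half a box edge the aggregate is presumed split across periodic
#' images and an error instructs the caller to unwrap.
#'
#' @param x An n x 3 coordinate matrix (A), or a [cg_configuration()].
#' @param masses Per-point masses (amu); taken from the bead table when `x`
#'   is a configuration. Massless (virtual) sites are ignored.
#' @param molecules When `x` is a configuration: molecule ids forming the
#'   aggregate (default all solute molecules).
#' @param box Box edges (A) for the split check; taken from the
#'   configuration when available.
#' @param unit_mass Use unit masses (geometry-only). Default `FALSE`.
#' @return List of class `shape_report`: `eigenvalues` (amu A^2, ascending),
#'   `axes` (columns = eigenvectors, right-handed), `com`, `n_points`,
#'   `total_mass`.
#' @examples
#' st <- place_stack(build_template(), stack_spec(6))
#' inertia_tensor(st)$eigenvalues
#' @export
inertia_tensor <- function(x, masses = NULL, molecules = NULL, box = NULL,
                           unit_mass = FALSE) {
  if (inherits(x, "cg_config")) {
    mols <- molecules %||% solute_molecules(x)
    b <- x$beads[x$beads$molecule %in% mols, ]
    box <- box %||% x$box
    masses <- if (unit_mass) as.numeric(!b$virtual) else b$mass
    x <- as.matrix(b[, c("x", "y", "z")])
  } else {
    x <- as.matrix(x)
    if (is.null(masses)) masses <- rep(1, nrow(x))
    if (unit_mass) masses <- rep(1, nrow(x))
  }
  keep <- masses > 0
  x <- x[keep, , drop = FALSE]
  masses <- masses[keep]
  if (nrow(x) < 2) abort("inertia tensor needs >= 2 massive beads.")
  if (!is.null(box)) {
    spread <- apply(x, 2, function(v) diff(range(v)))
    if (any(spread > box / 2)) {
      abort(paste("aggregate appears split across periodic images",
                  "(extent > half box); unwrap it first."))
    }
  }
  com <- colSums(x * masses) / sum(masses)
  r <- sweep(x, 2, com)
  r2 <- rowSums(r * r)
  I <- diag(c(sum(masses * r2), sum(masses * r2), sum(masses * r2))) -
    t(r) %*% (r * masses)
  e <- eigen((I + t(I)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  vals <- pmax(e$values[ord], 0)
  vecs <- e$vectors[, ord, drop = FALSE]
  if (det(vecs) < 0) vecs[, 3] <- -vecs[, 3]
  structure(list(eigenvalues = vals, axes = vecs, com = com,
                 n_points = nrow(x), total_mass = sum(masses)),
            class = "shape_report")
}

#' Classify aggregate shape from inertia eigenvalues
#'
#' With sorted eigenvalues `I1 <= I2 <= I3`:
#' near-spherical when `I1/I3 >= 1 - epsilon`; otherwise prolate when the
#' upper pair is the more degenerate one (`(I3-I2)/I3 < (I2-I1)/I2`: two
#' large, one small — rod-like), else oblate (two small, one large —
#' disc-like).  Scale-invariant and deterministic; always returns a label.
#'
#' @param report A `shape_report` (or a length-3 sorted eigenvalue vector).
#' @param epsilon Degeneracy threshold in `(0, 1)`. Default 0.25.
#' @return `"prolate"`, `"oblate"` or `"near-spherical"`.
#' @examples
#' classify_shape(c(1, 50, 51))  # prolate
#' classify_shape(c(25, 26, 50)) # oblate
#' @export
classify_shape <- function(report, epsilon = 0.25) {
  ev <- if (inherits(report, "shape_report")) report$eigenvalues else
    as.numeric(report)
  if (is.unsorted(ev)) abort("eigenvalues must be sorted ascending.")
  I1 <- ev[1]; I2 <- ev[2]; I3 <- ev[3]
  if (I3 <= 0) return("near-spherical")
  if (I1 / I3 >= 1 - epsilon) return("near-spherical")
  gap_hi <- (I3 - I2) / I3
  gap_lo <- if (I2 > 0) (I2 - I1) / I2 else 1
  if (gap_hi < gap_lo) "prolate" else "oblate"
}

#' Shape report for every aggregate in a configuration
#'
#' @param config A [cg_configuration()].
#' @param assignment An [cluster_molecules()] result; computed with defaults
#'   when `NULL`.
#' @param epsilon Threshold for [classify_shape()].
#' @param unit_mass Geometry-only (unit-mass) tensors. Default `FALSE`.
#' @return Tibble: `cluster`, `size`, `I1`, `I2`, `I3` (amu A^2), `label`,
#'   `ratio_12` (I1/I2), `ratio_23` (I2/I3).
#' @export
aggregate_shape_report <- function(config, assignment = NULL,
                                   epsilon = 0.25, unit_mass = FALSE) {
  if (is.null(assignment)) assignment <- cluster_molecules(config)
  purrr::map_dfr(split(assignment$labels$molecule,
                       assignment$labels$cluster), function(mols) {
    cl <- assignment$labels$cluster[match(mols[1],
                                          assignment$labels$molecule)]
    rep_ <- inertia_tensor(config, molecules = mols, unit_mass = unit_mass)
    ev <- rep_$eigenvalues
    tibble(cluster = cl, size = length(mols),
           I1 = ev[1], I2 = ev[2], I3 = ev[3],
           label = classify_shape(rep_, epsilon),
           ratio_12 = ifelse(ev[2] > 0, ev[1] / ev[2], NA_real_),
           ratio_23 = ifelse(ev[3] > 0, ev[2] / ev[3], NA_real_))
  })
}

# symmetry axis of a shape report: eigenvector of the most isolated
# eigenvalue, sign fixed toward the positive octant
symmetry_axis <- function(report) {
  ev <- report$eigenvalues
  k <- if ((ev[2] - ev[1]) > (ev[3] - ev[2])) 1L else 3L
  ax <- report$axes[, k]
  if (sum(ax) < 0) ax <- -ax
  ax
}
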