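#' Bead configuration in a periodic box
#'
#' A `cg_config` holds one snapshot: a per-bead tibble plus the orthorhombic
#' box.  Coordinates are stored in A with molecules kept whole (unwrapped);
#' periodic wrapping is applied only when writing coordinate files, so that
#' clustering, inertia tensors and Debye sums operate on intact molecules.
#'
#' @param beads Tibble with columns `molecule`, `site`, `name`, `type`,
#'   `role`, `x`, `y`, `z`, `virtual`, `radius`, `charge`, `mass`,
#'   `xray_contrast`, `neutron_contrast`.
#' @param box Numeric length-3 (or scalar, recycled) box edge lengths in A.
#' @param template The [build_template()] object molecules were built from
#'   (optional, `NULL` for ion-only or file-read configurations).
#' @param validate Check invariants (virtual-site residuals < 1e-6 A,
#'   per-molecule bead counts). Default `TRUE`.
#'
#' @return An object of class `cg_config`.
#' @export
cg_configuration <- function(beads, box, template = NULL, validate = TRUE) {
  box <- rep(as.numeric(box), length.out = 3)
  if (any(box <= 0)) abort("box edges must be positive (A).")
  need <- c("molecule", "site", "name", "type", "role", "x", "y", "z",
            "virtual", "radius", "charge", "mass",
            "xray_contrast", "neutron_contrast")
  missing_cols <- setdiff(need, names(beads))
  if (length(missing_cols)) {
    abort(paste("beads table missing columns:",
                paste(missing_cols, collapse = ", ")))
  }
  out <- structure(list(beads = as_tibble(beads), box = box,
                        template = template),
                   class = "cg_config")
  if (validate) validate_config(out)
  out
}

validate_config <- function(config, tol = 1e-6) {
  tpl <- config$template
  if (is.null(tpl)) return(invisible(config))
  n_tpl <- nrow(tpl$sites)
  mols <- split(seq_len(nrow(config$beads)), config$beads$molecule)
  for (idx in mols) {
    role1 <- config$beads$role[idx[1]]
    if (role1 %in% c("counterion", "solvent")) next
    if (length(idx) != n_tpl) {
      abort("per-molecule bead count does not match the template.")
    }
    xyz <- as.matrix(config$beads[idx, c("x", "y", "z")])
    res <- virtual_site_residual(xyz, tpl$virtual_rules)
    if (res > tol) {
      abort(sprintf("virtual-site residual %.2e A exceeds %.0e A", res, tol))
    }
  }
  invisible(config)
}

#' @export
print.cg_config <- function(x, ...) {
  cat("<cg_config> ", nrow(x$beads), " beads / ",
      dplyr::n_distinct(x$beads$molecule), " molecules, box ",
      paste(signif(x$box / A_PER_NM, 4), collapse = " x "), " nm\n", sep = "")
  invisible(x)
}

#' @exportS3Method tibble::as_tibble
as_tibble.cg_config <- function(x, ...) x$beads

config_coords <- function(config, rows = NULL) {
  b <- config$beads
  if (!is.null(rows)) b <- b[rows, ]
  as.matrix(b[, c("x", "y", "z")])
}

# solute molecule ids (skips counterions/solvent)
solute_molecules <- function(config) {
  b <- config$beads
  sort(unique(b$molecule[!(b$role %in% c("counterion", "solvent"))]))
}

#' Mass-weighted molecular centres of mass
#'
#' @param config A [cg_configuration()].
#' @param molecules Molecule ids; default all solute molecules.
#' @return Tibble `molecule`, `x`, `y`, `z` (A).
#' @export
molecule_com <- function(config, molecules = solute_molecules(config)) {
  b <- dplyr::filter(config$beads, .data$molecule %in% molecules,
                     .data$mass > 0)
  dplyr::summarise(
    dplyr::group_by(b, .data$molecule),
    x = weighted.mean(.data$x, .data$mass),
    y = weighted.mean(.data$y, .data$mass),
    z = weighted.mean(.data$z, .data$mass),
    .groups = "drop"
  )
}

# wrap bead coordinates into [0, box) by whole molecules (COM inside box)
wrap_config <- function(config) {
  com <- molecule_com(config, sort(unique(config$beads$molecule)))
  shift <- com
  for (k in 1:3) {
    col <- c("x", "y", "z")[k]
    shift[[col]] <- -config$box[k] * floor(com[[col]] / config$box[k])
  }
  b <- dplyr::left_join(config$beads, shift, by = "molecule",
                        suffix = c("", ".s"))
  b$x <- b$x + b$x.s; b$y <- b$y + b$y.s; b$z <- b$z + b$z.s
  config$beads <- dplyr::select(b, -dplyr::ends_with(".s"))
  config
}

#' Configuration ensemble
#'
#' An ordered set of [cg_configuration()] snapshots with (normalized)
#' statistical weights, the unit of ensemble averaging and refinement.
#'
#' @param configurations List of `cg_config` objects.
#' @param weights Nonnegative weights, recycled/normalized to sum 1.
#'   Default uniform.
#' @return Object of class `cg_ensemble`.
#' @export
cg_ensemble <- function(configurations, weights = NULL) {
  if (!length(configurations)) abort("ensemble needs >= 1 configuration.")
  ok <- vapply(configurations, inherits, logical(1), "cg_config")
  if (!all(ok)) abort("all ensemble members must be cg_config objects.")
  n <- length(configurations)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n) abort("one weight per configuration required.")
  if (any(weights < 0) || sum(weights) <= 0) {
    abort("weights must be nonnegative with positive sum.")
  }
  structure(list(configurations = configurations,
                 weights = weights / sum(weights)),
            class = "cg_ensemble")
}

#' @export
print.cg_ensemble <- function(x, ...) {
  cat("<cg_ensemble> ", length(x$configurations), " configurations\n",
      sep = "")
  invisible(x)
}

#' @export
length.cg_ensemble <- function(x) length(x$configurations)

as_ensemble <- function(x) {
  if (inherits(x, "cg_ensemble")) return(x)
  if (inherits(x, "cg_config")) return(cg_ensemble(list(x)))
  abort("expected a cg_config or cg_ensemble.")
}
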