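#' Small-angle scattering curve
#'
#' A (q, I, sigma[, dq]) table: strictly increasing q in 1/A, finite
#' intensities, positive uncertainties where present, optional per-point
#' Gaussian resolution width dq.
#'
#' @param q Scattering vector, 1/A, strictly increasing (sorted with a
#'   warning otherwise).
#' @param I Intensity (arbitrary units), finite.
#' @param sigma Optional per-point uncertainty (> 0 where present).
#' @param dq Optional per-point resolution width, 1/A (>= 0).
#' @return Tibble of class `sas_curve` with columns `q`, `I` and, when
#'   given, `sigma`, `dq`.
#' @examples
#' scattering_curve(q = c(0.01, 0.1, 1), I = c(100, 10, 1))
#' @export
scattering_curve <- function(q, I, sigma = NULL, dq = NULL) {
  if (length(q) != length(I)) abort("`q` and `I` lengths differ.")
  if (!all(is.finite(q)) || !all(is.finite(I))) {
    abort("`q` and `I` must be finite.")
  }
  if (is.unsorted(q, strictly = TRUE)) {
    warn("q not strictly increasing; sorting.")
    ord <- order(q)
    q <- q[ord]; I <- I[ord]
    if (!is.null(sigma)) sigma <- sigma[ord]
    if (!is.null(dq)) dq <- dq[ord]
    if (any(diff(q) == 0)) abort("duplicate q values.")
  }
  out <- tibble(q = q, I = I)
  if (!is.null(sigma)) {
    if (any(sigma <= 0)) abort("`sigma` must be > 0 where present.")
    out$sigma <- sigma
  }
  if (!is.null(dq)) {
    if (any(dq < 0)) abort("`dq` must be >= 0.")
    out$dq <- dq
  }
  class(out) <- c("sas_curve", class(out))
  out
}

#' Metainference effective-uncertainty model
#'
#' Per-point effective-uncertainty bounds: the maximum uncertainty is a
#' fraction `f_max` (default 0.7%) of the intensity at each point, the
#' minimum a fraction `f_min` (default 40%) of that maximum.  The current
#' value starts at the maximum and is sampled within the bounds during
#' refinement.
#'
#' @param curve A [scattering_curve()] (the data the model refers to).
#' @param f_max Maximum uncertainty as a fraction of intensity.
#'   Default 0.007.
#' @param f_min Minimum as a fraction of the maximum. Default 0.4.
#' @return Tibble of class `mi_uncertainty`: `q`, `sigma_min`, `sigma_max`,
#'   `sigma`.
#' @export
uncertainty_model <- function(curve, f_max = 0.007, f_min = 0.4) {
  if (f_max <= 0 || f_min <= 0 || f_min > 1) {
    abort("need f_max > 0 and f_min in (0, 1].")
  }
  if (any(curve$I <= 0)) {
    abort("intensities must be positive to set fractional uncertainties.")
  }
  s_max <- f_max * curve$I
  out <- tibble(q = curve$q, sigma_min = f_min * s_max, sigma_max = s_max,
                sigma = s_max)
  class(out) <- c("mi_uncertainty", class(out))
  out
}

#' Read a small-angle scattering curve from ASCII
#'
#' Whitespace-separated 2-, 3- or 4-column files (q, I[, sigma[, dq]]) with
#' `#` comment lines, the common exchange dialect of reduced SAXS/SANS
#' data.
#'
#' @param path File path.
#' @param q_unit `"A^-1"` (default) or `"nm^-1"` (converted by 0.1).
#' @return A [scattering_curve()].
#' @export
read_sas_curve <- function(path, q_unit = c("A^-1", "nm^-1")) {
  q_unit <- match.arg(q_unit)
  lines <- readLines(path)
  dat_lines <- grep("^\\s*(#|$)", lines, invert = TRUE)
  if (!length(dat_lines)) abort("no data rows in curve file.")
  fields <- strsplit(trimws(lines[dat_lines]), "\\s+")
  ncol <- unique(lengths(fields))
  if (length(ncol) != 1 || !(ncol %in% 2:4)) {
    abort("curve file must have a consistent 2-4 column layout.")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = ncol, byrow = TRUE)
  if (anyNA(m)) {
    bad <- dat_lines[which(rowSums(is.na(m)) > 0)[1]]
    abort(sprintf("non-numeric value in curve file at line %d.", bad))
  }
  q <- m[, 1]
  if (q_unit == "nm^-1") q <- q * 0.1
  scattering_curve(q, m[, 2],
                   sigma = if (ncol >= 3) m[, 3] else NULL,
                   dq = if (ncol >= 4) {
                     if (q_unit == "nm^-1") m[, 4] * 0.1 else m[, 4]
                   } else NULL)
}

#' Write a scattering curve as whitespace ASCII
#'
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @param comment Optional comment line(s), written with a `#` prefix.
#' @return `path`, invisibly.
#' @export
write_sas_curve <- function(curve, path, comment = NULL) {
  cols <- intersect(c("q", "I", "sigma", "dq"), names(curve))
  hdr <- c(paste0("# ", comment %||% character(0)),
           paste0("# ", paste(cols, collapse = " ")))
  body <- do.call(paste, c(unname(lapply(cols, function(cc) {
    formatC(curve[[cc]], format = "g", digits = 10)
  })), sep = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
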