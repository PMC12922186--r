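#' Spherical-bead form amplitude
#'
#' Homogeneous-sphere scattering amplitude
#' `f(q) = contrast * 3 [sin(qR) - qR cos(qR)] / (qR)^3`, where `contrast`
#' is the bead's excess scattering power over the displaced solvent
#' (effective electrons for X-rays, scattering length for neutrons): the
#' `delta_rho * V` prefactor absorbed into the bead table.  `f(0) =
#' contrast`, handled analytically (no 0/0).
#'
#' @param bead One row of [bead_types()] (or a bead type name).
#' @param q Scattering vector(s), 1/A (>= 0).
#' @param radiation `"xray"` or `"neutron"`.
#' @return Amplitude vector, same length as `q`.
#' @examples
#' bead_form_amplitude("SQ4n", c(0, 0.5, 2))
#' @export
bead_form_amplitude <- function(bead, q, radiation = c("xray", "neutron")) {
  radiation <- match.arg(radiation)
  if (is.character(bead)) bead <- bead_row(bead)
  contrast <- switch(radiation, xray = bead$xray_contrast,
                     neutron = bead$neutron_contrast)
  if (any(q < 0)) abort("`q` must be >= 0.")
  contrast * sphere_shape(q * bead$radius)
}

# 3 (sin x - x cos x) / x^3 with analytic small-x limit
sphere_shape <- function(x) {
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  out[small] <- 1 - x[small]^2 / 10
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

# sin(x)/x with limit 1
sinc_ <- function(x) {
  out <- rep(1, length(x))
  nz <- abs(x) > 1e-12
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

#' Debye-equation scattering intensity
#'
#' Orientation-averaged intensity of a rigid bead cluster:
#' `I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij) / (q r_ij)` with the
#' self term `f_i^2`, evaluated over free (non-periodic) distances — the
#' dilute-limit single-cluster form factor.  Distances are computed once;
#' per-bead amplitudes come from the spherical-bead model and the bead
#' table's radiation-specific contrasts.
#'
#' @param config A [cg_configuration()] (all solute + ion beads are used),
#'   or an n x 3 coordinate matrix.
#' @param q Scattering-vector grid, 1/A (> 0 or 0).
#' @param radiation `"xray"` or `"neutron"`.
#' @param types Bead type per coordinate row (required for a bare matrix).
#' @param bead_table Bead-type table. Default [bead_types()].
#' @param molecules Restrict to these molecule ids (configurations only).
#' @return A [scattering_curve()].
#' @examples
#' st <- place_stack(build_template(), stack_spec(4))
#' debye_intensity(st, q = c(0.05, 0.1, 0.5))
#' @export
debye_intensity <- function(config, q, radiation = c("xray", "neutron"),
                            types = NULL, bead_table = bead_types(),
                            molecules = NULL) {
  radiation <- match.arg(radiation)
  if (inherits(config, "cg_config")) {
    b <- config$beads
    if (!is.null(molecules)) b <- b[b$molecule %in% molecules, ]
    b <- b[b$role != "solvent", ]
    xyz <- as.matrix(b[, c("x", "y", "z")])
    types <- b$type
    if (!is.null(molecules)) {
      # single-aggregate mode: a spread beyond half the box means the
      # cluster is split across periodic images
      spread <- apply(xyz, 2, function(v) diff(range(v)))
      if (any(spread > 0.9 * config$box)) {
        abort("aggregate appears split across images; unwrap before scattering.")
      }
    }
  } else {
    xyz <- as.matrix(config)
    if (is.null(types)) abort("`types` required for bare coordinates.")
  }
  n <- nrow(xyz)
  if (n < 1) abort("need >= 1 bead.")
  if (any(q < 0)) abort("q must be >= 0.")

  info <- bead_row(unique(types), bead_table)
  tmap <- match(types, info$name)
  contrast <- switch(radiation, xray = info$xray_contrast,
                     neutron = info$neutron_contrast)
  # per unique type amplitude at each q: nq x ntype
  f_type <- outer(q, info$radius, function(qq, rr) sphere_shape(qq * rr)) *
    rep(contrast, each = length(q))

  I <- numeric(length(q))
  if (n == 1) {
    I <- f_type[, tmap[1]]^2
    return(scattering_curve(q, I))
  }
  d <- as.vector(dist(xyz))           # condensed pair distances
  pi_ <- rep(seq_len(n - 1), times = (n - 1):1)
  pj_ <- unlist(lapply(2:n, function(k) k:n), use.names = FALSE)
  ti <- tmap[pi_]; tj <- tmap[pj_]
  for (k in seq_along(q)) {
    f <- f_type[k, ]
    I[k] <- sum(f[tmap]^2) + 2 * sum(f[ti] * f[tj] * sinc_(q[k] * d))
  }
  scattering_curve(q, I)
}

#' Ensemble-averaged scattering intensity
#'
#' Weighted mean of per-configuration Debye intensities; linear in the
#' weights, so refinement can reweight precomputed member curves.
#'
#' @param ensemble A [cg_ensemble()].
#' @param q q grid, 1/A.
#' @param radiation `"xray"` or `"neutron"`.
#' @param weights Optional weights overriding the ensemble's (normalized).
#' @param ... Passed to [debye_intensity()].
#' @return A [scattering_curve()].
#' @export
ensemble_average_intensity <- function(ensemble, q,
                                       radiation = c("xray", "neutron"),
                                       weights = NULL, ...) {
  radiation <- match.arg(radiation)
  ens <- as_ensemble(ensemble)
  w <- weights %||% ens$weights
  if (any(w < 0) || sum(w) <= 0) {
    abort("weights must be nonnegative with positive sum.")
  }
  w <- w / sum(w)
  I <- Reduce(`+`, purrr::map2(ens$configurations, w, function(cfg, wi) {
    wi * debye_intensity(cfg, q, radiation, ...)$I
  }))
  scattering_curve(q, I)
}

#' Gaussian resolution smearing
#'
#' Convolves the intensity with a Gaussian in q of per-point width `dq`
#' (instrumental resolution), evaluated on the curve's own grid with
#' trapezoid quadrature and renormalized kernels.  `dq = 0` points are
#' returned unchanged; a constant curve is invariant; positivity is
#' preserved.  Points whose kernel covers fewer than 3 grid points fall
#' back to the unsmeared value with a warning.
#'
#' @param curve A [scattering_curve()].
#' @param dq Per-point width (1/A), a scalar width, or `NULL` to use the
#'   curve's `dq` column.
#' @param dq_fraction Alternatively, a global fractional width
#'   (`dq = dq_fraction * q`).
#' @return A smeared [scattering_curve()] (keeps `sigma`/`dq` columns).
#' @export
smear <- function(curve, dq = NULL, dq_fraction = NULL) {
  q <- curve$q
  if (!is.null(dq_fraction)) dq <- dq_fraction * q
  if (is.null(dq)) dq <- curve[["dq"]]
  if (is.null(dq)) abort("no `dq` given and curve has no dq column.")
  dq <- rep(dq, length.out = length(q))
  if (any(dq < 0)) abort("`dq` must be >= 0.")
  I_out <- curve$I
  fellback <- FALSE
  for (i in seq_along(q)) {
    if (dq[i] == 0) next
    support <- which(abs(q - q[i]) <= 4 * dq[i])
    if (length(support) < 3) {
      fellback <- TRUE
      next
    }
    w <- exp(-(q[support] - q[i])^2 / (2 * dq[i]^2))
    tw <- trap_weights(q[support]) * w
    I_out[i] <- sum(tw * curve$I[support]) / sum(tw)
  }
  if (fellback) {
    warn("q grid too coarse for some dq; those points left unsmeared.")
  }
  out <- curve
  out$I <- I_out
  out
}

# trapezoid quadrature weights for an ascending grid
trap_weights <- function(x) {
  n <- length(x)
  if (n == 1) return(1)
  h <- diff(x)
  c(h[1] / 2, (head(h, -1) + tail(h, -1)) / 2, h[n - 1] / 2)
}

# interpolate a model curve onto a q grid, linear in (log q, log I)
interp_model <- function(model, q_out, floor_ = 1e-300) {
  I_pos <- pmax(model$I, floor_)
  yi <- approx(log(model$q), log(I_pos), xout = log(q_out), rule = 2)$y
  exp(yi)
}

#' Fit scale and offset of a model curve to data
#'
#' Weighted least squares for `data ~ s * model + c` with weights
#' `1/sigma^2`: the closed-form normal equations, exact on noiseless
#' synthetic data.  The model is interpolated to the data grid linearly in
#' (log q, log I).
#'
#' @param model Model [scattering_curve()].
#' @param data Data [scattering_curve()].
#' @param sigma Per-point uncertainties; defaults to the data's `sigma`
#'   column, else unit weights.
#' @return List of class `sas_fit`: `s`, `c`, `chi2` (reduced), `n`,
#'   `residuals` tibble (`q`, `resid`, `sigma`).
#' @export
fit_scale_offset <- function(model, data, sigma = NULL) {
  sigma <- sigma %||% data[["sigma"]] %||% rep(1, nrow(data))
  if (any(sigma <= 0)) abort("`sigma` must be > 0.")
  m <- if (isTRUE(all.equal(model$q, data$q))) model$I else
    interp_model(model, data$q)
  if (max(m) - min(m) <= 1e-14 * max(abs(m), 1)) {
    abort("degenerate (constant) model: scale/offset not identifiable.")
  }
  w <- 1 / sigma^2
  sw <- sum(w); swm <- sum(w * m); swd <- sum(w * data$I)
  swmm <- sum(w * m * m); swmd <- sum(w * m * data$I)
  det_ <- sw * swmm - swm^2
  s <- (sw * swmd - swm * swd) / det_
  c_ <- (swmm * swd - swm * swmd) / det_
  resid <- s * m + c_ - data$I
  structure(list(
    s = s, c = c_,
    chi2 = sum((resid / sigma)^2) / length(resid),
    n = length(resid),
    residuals = tibble(q = data$q, resid = resid, sigma = sigma)
  ), class = "sas_fit")
}

#' @export
print.sas_fit <- function(x, ...) {
  cat(sprintf("<sas_fit> s = %.6g, c = %.6g, reduced chi2 = %.4g (n = %d)\n",
              x$s, x$c, x$chi2, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sas_fit <- function(x, ...) {
  tibble(term = c("scale", "offset"), estimate = c(x$s, x$c))
}

#' @exportS3Method generics::glance
glance.sas_fit <- function(x, ...) {
  tibble(chi2 = x$chi2, n = x$n)
}

#' Chi-squared agreement between model and data
#'
#' `chi2 = (1/N) sum_i (s I_model,i + c - I_data,i)^2 / sigma_i^2` on a
#' common q grid, with the effective uncertainties of an
#' [uncertainty_model()] (its current `sigma`), a plain sigma vector, or
#' the data's own column.  Reduced (divided by the number of points) by
#' default; set `reduced = FALSE` for the raw sum.
#'
#' @param model,data [scattering_curve()]s on a common grid (the model is
#'   interpolated otherwise).
#' @param unc An [uncertainty_model()], or a numeric sigma vector.
#' @param s,c Scale and offset applied to the model. Default 1, 0.
#' @param reduced Divide by the number of points. Default `TRUE`.
#' @return Nonnegative scalar.
#' @export
chi2 <- function(model, data, unc = NULL, s = 1, c = 0, reduced = TRUE) {
  sigma <- if (inherits(unc, "mi_uncertainty")) unc$sigma
  else unc %||% data[["sigma"]]
  if (is.null(sigma)) abort("no uncertainties available for chi2.")
  if (any(sigma == 0)) abort("sigma must be nonzero.")
  m <- if (isTRUE(all.equal(model$q, data$q))) model$I else
    interp_model(model, data$q)
  val <- sum(((s * m + c - data$I) / sigma)^2)
  if (reduced) val / length(data$q) else val
}

#' Select q points for refinement
#'
#' Picks `n_points` log-evenly spaced points inside a q window, defaulting
#' to the region around the structure peak near q ~ 0.1 1/A where
#' refinement is informative.  Duplicate nearest-grid hits are resolved to
#' distinct indices.
#'
#' @param curve A [scattering_curve()].
#' @param n_points Number of points (<= number of q values). Default 20.
#' @param window Length-2 q window (1/A); default `[0.03, 0.6]` clipped to
#'   the data range.
#' @return Integer indices into `curve$q`.
#' @export
select_q_points <- function(curve, n_points = 20, window = NULL) {
  q <- curve$q
  if (n_points > length(q)) abort("`n_points` exceeds curve length.")
  if (is.null(window)) {
    window <- c(max(min(q), 0.03), min(max(q), 0.6))
    if (window[1] >= window[2]) window <- range(q)
  }
  if (window[1] < min(q) - 1e-12 || window[2] > max(q) + 1e-12) {
    abort("q window lies outside the data range.")
  }
  inside <- which(q >= window[1] & q <= window[2])
  if (length(inside) < n_points) abort("window holds fewer points than requested.")
  if (n_points == 1) {
    centre <- sqrt(window[1] * window[2])
    return(inside[which.min(abs(log(q[inside]) - log(centre)))])
  }
  targets <- exp(seq(log(window[1]), log(window[2]), length.out = n_points))
  idx <- integer(n_points)
  taken <- logical(length(q))
  for (k in seq_along(targets)) {
    cand <- inside[!taken[inside]]
    j <- cand[which.min(abs(log(q[cand]) - log(targets[k])))]
    idx[k] <- j
    taken[j] <- TRUE
  }
  sort(idx)
}
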