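#' Metainference energy
#'
#' Negative log-posterior of the Gaussian-noise metainference model for one
#' or more curves:
#' `E = sum_i [ (s <I_i>_w + c - d_i)^2 / (2 sigma_i^2) + ln sigma_i ]`,
#' where `<I_i>_w` is the weights-averaged model intensity at data point i.
#' Scale and offset carry flat priors within bounds; each per-point
#' effective uncertainty is restricted to its `[sigma_min, sigma_max]` box
#' (enforced by the proposals, asserted here).  The `ln sigma` term is the
#' Gaussian normalization that keeps sigma from drifting to its maximum
#' trivially.
#'
#' @param state A refinement state, see [refine()]: list with `weights` and
#'   per-curve `s`, `c`, `sigma`.
#' @param models List (per curve) of n_config x n_q model intensity
#'   matrices.
#' @param data List (per curve) of data intensity vectors at the selected
#'   q points.
#' @param unc List (per curve) of [uncertainty_model()] tibbles (bounds).
#' @return Scalar energy.
#' @export
mi_energy <- function(state, models, data, unc) {
  E <- 0
  for (k in seq_along(models)) {
    sig <- state$sigma[[k]]
    if (any(sig < unc[[k]]$sigma_min - 1e-12) ||
        any(sig > unc[[k]]$sigma_max + 1e-12)) {
      abort("sigma outside its [sigma_min, sigma_max] bounds.")
    }
    mean_I <- as.vector(state$weights %*% models[[k]])
    resid <- state$s[k] * mean_I + state$c[k] - data[[k]]
    E <- E + sum(resid^2 / (2 * sig^2) + log(sig))
  }
  E
}

new_state <- function(n_config, curves_unc, s0, c0) {
  list(
    weights = rep(1 / n_config, n_config),
    s = s0, c = c0,
    sigma = purrr::map(curves_unc, ~ .x$sigma_max)
  )
}

#' One Metropolis move of the metainference sampler
#'
#' Proposes a uniform displacement in one move class and accepts or rejects
#' on [mi_energy()].  Move classes: `"sigma"` (one random data point of one
#' curve, reflective at its bounds), `"scale"` and `"offset"` (one curve,
#' flat prior within broad bounds), `"weights"` (pairwise mass transfer on
#' the simplex, which preserves the weight sum exactly).  Rejected moves
#' leave the state unchanged.
#'
#' @param state Current state (see [mi_energy()]).
#' @param move Move class.
#' @param models,data,unc As in [mi_energy()].
#' @param steps Named list of step sizes
#'   (`sigma`, `scale`, `offset`, `weights`).
#' @param energy Current energy (recomputed when `NULL`).
#' @return List `state`, `energy`, `accepted` (logical).
#' @export
mc_step <- function(state, move = c("sigma", "scale", "offset", "weights"),
                    models, data, unc, steps, energy = NULL) {
  move <- match.arg(move)
  if (is.null(energy)) energy <- mi_energy(state, models, data, unc)
  prop <- state
  k <- sample.int(length(models), 1)
  if (move == "sigma") {
    i <- sample.int(length(prop$sigma[[k]]), 1)
    lo <- unc[[k]]$sigma_min[i]; hi <- unc[[k]]$sigma_max[i]
    x <- prop$sigma[[k]][i] + runif(1, -steps$sigma, steps$sigma) *
      (hi - lo)
    x <- reflect(x, lo, hi)
    if (is.na(x)) {
      return(list(state = state, energy = energy, accepted = FALSE))
    }
    prop$sigma[[k]][i] <- x
  } else if (move == "scale") {
    # symmetric proposal (constant span) so detailed balance holds
    span <- state$s_ref[k] %||% 1
    x <- prop$s[k] + runif(1, -steps$scale, steps$scale) * span
    if (x <= 0) return(list(state = state, energy = energy,
                            accepted = FALSE))
    prop$s[k] <- x
  } else if (move == "offset") {
    span <- max(abs(data[[k]])) + 1e-12
    prop$c[k] <- prop$c[k] + runif(1, -steps$offset, steps$offset) * span
  } else {
    if (length(prop$weights) < 2) {
      return(list(state = state, energy = energy, accepted = TRUE))
    }
    ij <- sample.int(length(prop$weights), 2)
    delta <- runif(1, -steps$weights, steps$weights)
    wi <- prop$weights[ij[1]] + delta
    wj <- prop$weights[ij[2]] - delta
    if (wi < 0 || wj < 0) {
      return(list(state = state, energy = energy, accepted = FALSE))
    }
    prop$weights[ij[1]] <- wi
    prop$weights[ij[2]] <- wj
  }
  e_new <- mi_energy(prop, models, data, unc)
  if (e_new <= energy || runif(1) < exp(energy - e_new)) {
    list(state = prop, energy = e_new, accepted = TRUE)
  } else {
    list(state = state, energy = energy, accepted = FALSE)
  }
}

# single-fold reflection at the bounds: a symmetric proposal map
# (x -> 2*lo - x below lo, 2*hi - x above hi); NA when still outside,
# which the caller counts as a rejection
reflect <- function(x, lo, hi) {
  if (hi <= lo) return(lo)
  if (x < lo) x <- 2 * lo - x
  if (x > hi) x <- 2 * hi - x
  if (x < lo || x > hi) return(NA_real_)
  x
}

#' Metainference ensemble refinement
#'
#' Desk-scale metainference: reweights a fixed configuration library
#' against one or more target scattering curves by Metropolis Monte Carlo,
#' jointly sampling the ensemble weights (simplex), per-curve scale and
#' offset, and per-point effective uncertainties within their bounds.
#' Step sizes adapt during burn-in toward ~50% acceptance, then freeze so
#' the production chain is Markovian.  Multiple curves (e.g. SAXS + SANS)
#' enter as a plain sum of per-curve energies.
#'
#' @param ensemble A [cg_ensemble()] with >= 2 configurations.
#' @param data A [scattering_curve()] or list of them; names become curve
#'   labels (`curve1`, ... otherwise).
#' @param radiation Radiation per curve, recycled (`"xray"`/`"neutron"`).
#' @param unc Optional [uncertainty_model()] (or list, per curve); built
#'   with defaults from each curve otherwise.
#' @param n_steps Total MC steps. Default 20000.
#' @param n_points q points selected per curve ([select_q_points()]).
#' @param seed RNG seed (bit-reproducible results).
#' @param burn_in Fraction of steps used for burn-in/adaptation (staged:
#'   equilibration, then scale/offset/weight step tuning, then sigma step
#'   tuning under the production move mix). Default 0.4.
#' @param thin Keep every `thin`-th post-burn-in sample in the trace.
#' @param apply_smearing Smear model curves with the data's `dq` column
#'   when present. Default `TRUE`.
#' @param initial_steps Optional named list overriding the initial step
#'   sizes (`sigma`, `scale`, `offset`, `weights`).
#' @param adapt Adapt step sizes during burn-in. Default `TRUE`.
#' @return Object of class `mi_refinement`: posterior-mean `weights`, per
#'   curve best-fit `s`, `c`, posterior-mean `sigma`, reduced `chi2` at
#'   the posterior means, acceptance rates, a thinned `trace` tibble, and
#'   the selected q points.
#' @examples
#' \donttest{
#' tpl <- build_template()
#' ens <- build_ensemble(ensemble_recipe(n_molecules = 6, seed = 1), tpl,
#'                       n_configurations = 3)
#' target <- ensemble_average_intensity(ens, q = seq(0.05, 0.5, length = 30))
#' fit <- refine(ens, target, n_steps = 2000, n_points = 10, seed = 1)
#' }
#' @export
refine <- function(ensemble, data, radiation = "xray", unc = NULL,
                   n_steps = 20000, n_points = 20, seed = 1,
                   burn_in = 0.4, thin = 10, apply_smearing = TRUE,
                   initial_steps = NULL, adapt = TRUE) {
  ens <- as_ensemble(ensemble)
  n_config <- length(ens$configurations)
  if (n_config < 2) abort("refinement needs >= 2 configurations.")
  if (inherits(data, "sas_curve")) data <- list(data)
  n_curve <- length(data)
  radiation <- rep(radiation, length.out = n_curve)
  if (!is.null(unc) && inherits(unc, "mi_uncertainty")) unc <- list(unc)
  if (n_steps < 100) abort("`n_steps` too small.")

  set.seed(as.integer(seed))
  sel <- vector("list", n_curve)
  models <- vector("list", n_curve)
  dvec <- vector("list", n_curve)
  uncs <- vector("list", n_curve)
  for (k in seq_len(n_curve)) {
    npk <- min(n_points, nrow(data[[k]]))
    sel[[k]] <- select_q_points(data[[k]], npk)
    dk <- data[[k]][sel[[k]], ]
    dvec[[k]] <- dk$I
    uk <- if (!is.null(unc)) unc[[k]][sel[[k]], ] else uncertainty_model(dk)
    uncs[[k]] <- uk
    M <- matrix(0, n_config, npk)
    for (i in seq_len(n_config)) {
      cur <- debye_intensity(ens$configurations[[i]], data[[k]]$q,
                             radiation[k])
      dqcol <- data[[k]][["dq"]]
      if (apply_smearing && !is.null(dqcol)) {
        cur <- smear(cur, dq = dqcol)
      }
      M[i, ] <- cur$I[sel[[k]]]
    }
    models[[k]] <- M
  }

  # initial scale/offset from the closed-form fit at uniform weights
  s0 <- numeric(n_curve); c0 <- numeric(n_curve)
  for (k in seq_len(n_curve)) {
    mean_I <- colMeans(models[[k]])
    fit0 <- fit_scale_offset(
      scattering_curve(data[[k]]$q[sel[[k]]], pmax(mean_I, 1e-300)),
      scattering_curve(data[[k]]$q[sel[[k]]], dvec[[k]]),
      sigma = uncs[[k]]$sigma_max)
    s0[k] <- max(fit0$s, 1e-6); c0[k] <- fit0$c
  }
  state <- new_state(n_config, uncs, s0, c0)
  state$s_ref <- s0
  energy <- mi_energy(state, models, dvec, uncs)

  steps <- list(sigma = 2.5, scale = 0.05, offset = 0.02, weights = 0.1)
  for (nm in names(initial_steps)) steps[[nm]] <- initial_steps[[nm]]
  classes <- c("sigma", "scale", "offset", "weights")
  n_burn <- floor(burn_in * n_steps)
  acc <- setNames(numeric(4), classes)   # post-burn-in acceptance counts
  tot <- setNames(numeric(4), classes)
  acc_b <- setNames(numeric(4), classes) # within-adaptation-window counts
  tot_b <- setNames(numeric(4), classes)
  n_win <- setNames(numeric(4), classes) # completed adaptation windows
  adapt_window <- 120                    # attempts per class per window

  w_sum <- numeric(n_config)
  s_sum <- numeric(n_curve); c_sum <- numeric(n_curve)
  sig_sum <- purrr::map(uncs, ~ numeric(nrow(.x)))
  n_samp <- 0
  trace <- list()

  # burn-in is staged so each move class is tuned under conditions close
  # to production: (A) plain equilibration, (B) adapt scale/offset/weights,
  # (C) adapt the sigma step last, under the production move mix
  phase_a <- floor(0.2 * n_burn)
  phase_b <- floor(0.5 * n_burn)
  for (t in seq_len(n_steps)) {
    mv <- classes[sample.int(4, 1)]
    res <- mc_step(state, mv, models, dvec, uncs, steps, energy)
    state <- res$state; energy <- res$energy
    if (t <= n_burn) {
      if (!adapt || t <= phase_a) next
      tune <- if (t <= phase_b) c("scale", "offset", "weights") else "sigma"
      if (!(mv %in% tune)) next
      acc_b[mv] <- acc_b[mv] + res$accepted
      tot_b[mv] <- tot_b[mv] + 1
      if (tot_b[mv] >= adapt_window) {
        # high-gain acquisition first (the acceptance-vs-step response is
        # shallow), then Robbins-Monro decay so the step converges
        n_win[mv] <- n_win[mv] + 1
        rate <- acc_b[mv] / tot_b[mv]
        gain <- 5 / max(1, n_win[mv] - 2)
        adj <- max(-0.6, min(0.6, gain * (rate - 0.5)))
        steps[[mv]] <- steps[[mv]] * exp(adj)
        acc_b[mv] <- 0; tot_b[mv] <- 0
      }
    } else {
      acc[mv] <- acc[mv] + res$accepted
      tot[mv] <- tot[mv] + 1
      w_sum <- w_sum + state$weights
      s_sum <- s_sum + state$s; c_sum <- c_sum + state$c
      for (k in seq_len(n_curve)) {
        sig_sum[[k]] <- sig_sum[[k]] + state$sigma[[k]]
      }
      n_samp <- n_samp + 1
      if ((t - n_burn) %% thin == 0) {
        trace[[length(trace) + 1]] <- tibble(
          step = t, energy = energy,
          s = state$s[1], c = state$c[1],
          weight_1 = state$weights[1]
        )
      }
    }
  }

  w_mean <- w_sum / n_samp
  s_mean <- s_sum / n_samp
  c_mean <- c_sum / n_samp
  sig_mean <- purrr::map(sig_sum, ~ .x / n_samp)
  chi2s <- numeric(n_curve)
  for (k in seq_len(n_curve)) {
    mean_I <- as.vector(w_mean %*% models[[k]])
    chi2s[k] <- sum(((s_mean[k] * mean_I + c_mean[k] - dvec[[k]]) /
                       sig_mean[[k]])^2) / length(dvec[[k]])
  }
  labels <- names(data) %||% paste0("curve", seq_len(n_curve))
  if (is.null(names(data)) || any(names(data) == "")) {
    labels <- paste0("curve", seq_len(n_curve))
  }
  structure(list(
    weights = w_mean,
    fits = tibble(curve = labels, s = s_mean, c = c_mean, chi2 = chi2s),
    sigma = setNames(sig_mean, labels),
    acceptance = acc / pmax(tot, 1),
    step_sizes = steps,
    trace = dplyr::bind_rows(trace),
    q_points = purrr::map2(data, sel, ~ .x$q[.y]),
    n_steps = n_steps, n_burn = n_burn, seed = seed
  ), class = "mi_refinement")
}

#' @export
print.mi_refinement <- function(x, ...) {
  cat("<mi_refinement> ", length(x$weights), " configurations, ",
      nrow(x$fits), " curve(s)\n", sep = "")
  cat("  reduced chi2:", paste(sprintf("%s %.3g", x$fits$curve,
                                       x$fits$chi2), collapse = ", "), "\n")
  cat("  sigma-move acceptance:", sprintf("%.2f", x$acceptance["sigma"]),
      "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mi_refinement <- function(x, ...) {
  tibble(configuration = seq_along(x$weights), weight = x$weights)
}

#' @exportS3Method generics::glance
glance.mi_refinement <- function(x, ...) {
  tibble(n_configurations = length(x$weights),
         n_curves = nrow(x$fits),
         chi2_mean = mean(x$fits$chi2),
         sigma_acceptance = unname(x$acceptance["sigma"]),
         n_steps = x$n_steps)
}
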