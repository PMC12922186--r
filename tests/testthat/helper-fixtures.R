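# shared fixtures, built in code at test time

# one template reused across tests (geometry is deterministic)
tpl_fixture <- build_template()

# random free-floating bead cluster (coordinates + types), for Debye and
# inertia oracles
random_cluster <- function(n, spread = 30, types = c("TC5e", "SQ4n", "SC1")) {
  list(xyz = matrix(runif(3 * n, -spread, spread), ncol = 3),
       types = sample(types, n, replace = TRUE))
}

# brute-force Debye sum: explicit full double loop over bead pairs,
# independent of the package implementation
debye_brute <- function(xyz, types, q, radiation = "xray") {
  bt <- bead_types()
  idx <- match(types, bt$name)
  contrast <- if (radiation == "xray") bt$xray_contrast else bt$neutron_contrast
  n <- nrow(xyz)
  sapply(q, function(qk) {
    shape <- function(x) ifelse(abs(x) < 1e-8, 1,
                                3 * (sin(x) - x * cos(x)) / x^3)
    f <- contrast[idx] * shape(qk * bt$radius[idx])
    acc <- 0
    for (i in seq_len(n)) {
      dx <- sweep(xyz, 2, xyz[i, ])
      r <- sqrt(rowSums(dx^2))
      s <- ifelse(r < 1e-12, 1, sin(qk * r) / (qk * r))
      if (qk == 0) s <- rep(1, n)
      acc <- acc + sum(f[i] * f * s)
    }
    acc
  })
}

# analytic homogeneous-sphere intensity, normalized to I(0) = 1
sphere_intensity <- function(q, R) {
  x <- q * R
  (3 * (sin(x) - x * cos(x)) / x^3)^2
}

# analytic SASA of two intersecting spheres of equal accessible radius r
# at centre distance d (< 2r): total area minus the two spherical caps
two_sphere_sasa <- function(r, d) {
  h <- r - d / 2            # cap height removed on each sphere
  2 * (4 * pi * r^2) - 2 * (2 * pi * r * h)
}

# two-population library (4-stacks vs monomer boxes) and its component
# mean intensities; used by refinement tests and acceptance checks
two_population_library <- function(q, n_each = 4) {
  mk_stack <- function(s) {
    set.seed(s)
    place_stack(tpl_fixture, stack_spec(4, jitter_sigma = 0.4),
                seed = s, box = 300)
  }
  mk_mono <- function(s) {
    set.seed(s)
    build_ensemble(ensemble_recipe(n_molecules = 4, monomer_fraction = 1,
                                   seed = s), tpl_fixture)$configurations[[1]]
  }
  lib <- cg_ensemble(c(lapply(seq_len(n_each), mk_stack),
                       lapply(n_each + seq_len(n_each), mk_mono)))
  I_stack <- ensemble_average_intensity(
    cg_ensemble(lib$configurations[seq_len(n_each)]), q)$I
  I_mono <- ensemble_average_intensity(
    cg_ensemble(lib$configurations[n_each + seq_len(n_each)]), q)$I
  list(lib = lib, I_stack = I_stack, I_mono = I_mono, n_each = n_each)
}

expect_tol <- function(x, y, tol) expect_true(max(abs(x - y)) < tol)
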