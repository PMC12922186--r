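test_that("spherical-bead amplitude has the right limits and zeros", {
  bt <- bead_types()
  sq <- bt[bt$name == "SQ4n", ]
  f0 <- bead_form_amplitude(sq, 0)
  expect_equal(f0, sq$xray_contrast)               # f(0) = contrast, no 0/0
  expect_equal(bead_form_amplitude(sq, 1e-9), f0, tolerance = 1e-12)
  # first zero of the sphere amplitude at qR = 4.4934...
  x0 <- 4.4934095
  q_lo <- (x0 - 0.05) / sq$radius; q_hi <- (x0 + 0.05) / sq$radius
  expect_gt(bead_form_amplitude(sq, q_lo), 0)
  expect_lt(bead_form_amplitude(sq, q_hi), 0)
  # zero-contrast bead scatters nothing
  w <- bt[bt$name == "W", ]
  expect_equal(bead_form_amplitude(w, c(0, 0.1, 1)), c(0, 0, 0))
  expect_equal(bead_form_amplitude("SQ4n", 0.3, "neutron"),
               sq$neutron_contrast *
                 stacksas:::sphere_shape(0.3 * sq$radius))
  expect_error(bead_form_amplitude(sq, -0.1), "q")
})

test_that("Debye intensity reproduces analytic one- and two-bead forms", {
  q <- c(0.01, 0.05, 0.2, 0.8, 1.5)
  one <- debye_intensity(matrix(0, 1, 3), q, types = "TC5e")
  f <- bead_form_amplitude("TC5e", q)
  expect_equal(one$I, f^2, tolerance = 1e-12)

  r12 <- 7
  two <- debye_intensity(rbind(c(0, 0, 0), c(r12, 0, 0)), q, types = rep("TC5e", 2))
  expect_equal(two$I, 2 * f^2 * (1 + sin(q * r12) / (q * r12)),
               tolerance = 1e-12)

  # forward limit I(0) = (sum f(0))^2
  set.seed(73)
  cl <- random_cluster(40)
  I0 <- debye_intensity(cl$xyz, 0, types = cl$types)$I
  f0 <- sapply(cl$types, function(tp) bead_form_amplitude(tp, 0))
  expect_equal(I0, sum(f0)^2, tolerance = 1e-9 * I0)
})

test_that("optimized Debye sum equals the brute-force double loop", {
  set.seed(79)
  q <- c(0.02, 0.1, 0.4, 1.2)
  for (trial in 1:15) {
    cl <- random_cluster(sample(10:80, 1))
    mine <- debye_intensity(cl$xyz, q, types = cl$types)$I
    oracle <- debye_brute(cl$xyz, cl$types, q)
    expect_equal(mine, oracle, tolerance = 1e-10)
  }
})

test_that("Debye intensity is invariant under rigid motion and relabeling", {
  set.seed(83)
  q <- c(0.05, 0.3, 1)
  cl <- random_cluster(50)
  I0 <- debye_intensity(cl$xyz, q, types = cl$types)$I
  moved <- stacksas:::rigid_transform(cl$xyz, stacksas:::random_rotation(),
                                      runif(3, -40, 40))
  expect_equal(debye_intensity(moved, q, types = cl$types)$I, I0,
               tolerance = 1e-9 * max(I0))
  perm <- sample(nrow(cl$xyz))
  expect_equal(debye_intensity(cl$xyz[perm, ], q, types = cl$types[perm])$I,
               I0, tolerance = 1e-9 * max(I0))
})

test_that("a dense bead-filled sphere approaches the analytic sphere curve", {
  R <- 18; a <- 2
  g <- seq(-R, R, by = a)
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  pts <- pts[rowSums(pts^2) <= R^2, ]
  q <- seq(0.02, pi / R, length.out = 12)
  # identical point-like scatterers: use a tiny bead so the form factor is
  # flat over the tested q range
  bt <- bead_types()
  mine <- debye_intensity(pts, q, types = rep("TC5e", nrow(pts)))$I
  shape_corr <- stacksas:::sphere_shape(q * bt$radius[bt$name == "TC5e"])^2
  ratio <- (mine / shape_corr) / (mine[1] / shape_corr[1])
  analytic <- sphere_intensity(q, R) / sphere_intensity(q[1], R)
  expect_lt(max(abs(ratio - analytic) / analytic), 0.02)
})

test_that("ensemble averaging is linear in the weights", {
  q <- c(0.05, 0.2, 0.6)
  c1 <- place_stack(tpl_fixture, stack_spec(2), box = 200)
  c2 <- place_stack(tpl_fixture, stack_spec(5), box = 200)
  I1 <- debye_intensity(c1, q)$I; I2 <- debye_intensity(c2, q)$I
  ens <- cg_ensemble(list(c1, c2))
  expect_equal(ensemble_average_intensity(ens, q)$I, (I1 + I2) / 2)
  expect_equal(ensemble_average_intensity(ens, q, weights = c(1, 0))$I, I1)
  expect_equal(ensemble_average_intensity(ens, q, weights = c(0.3, 0.7))$I,
               0.3 * I1 + 0.7 * I2, tolerance = 1e-12)
  expect_error(ensemble_average_intensity(ens, q, weights = c(0, 0)),
               "weights")
})

test_that("smearing is identity at dq = 0 and matches direct convolution", {
  q <- seq(0.02, 1, length.out = 120)
  set.seed(89)
  I <- exp(-q * 3) * (2 + sin(12 * q)) + 0.1
  cur <- scattering_curve(q, I)
  expect_equal(smear(cur, dq = 0)$I, I)
  # constant curve is invariant under any smearing
  flat <- scattering_curve(q, rep(4, length(q)))
  expect_equal(smear(flat, dq = 0.05)$I, rep(4, length(q)), tolerance = 1e-9)
  # direct numerical convolution oracle on the same grid
  dq0 <- 0.03
  sm <- smear(cur, dq = dq0)
  for (i in c(30, 60, 90)) {
    kern <- exp(-(q - q[i])^2 / (2 * dq0^2))
    kern[abs(q - q[i]) > 4 * dq0] <- 0
    w <- stacksas:::trap_weights(q) * kern
    # the implementation integrates on the truncated support, the oracle on
    # the full grid: identical up to edge quadrature weights
    expect_equal(sm$I[i], sum(w * I) / sum(w), tolerance = 1e-4)
  }
  expect_true(all(sm$I > 0))
  expect_warning(smear(scattering_curve(c(0.1, 0.5, 1), c(3, 2, 1)),
                       dq = 0.001), "coarse")
})

test_that("scale/offset fit is exact on transformed data", {
  q <- seq(0.03, 0.9, length.out = 40)
  I <- 100 * exp(-q * 4) + 5
  model <- scattering_curve(q, I)
  data <- scattering_curve(q, 2 * I + 5)
  fit <- fit_scale_offset(model, data)
  expect_equal(fit$s, 2, tolerance = 1e-12)
  expect_equal(fit$c, 5, tolerance = 1e-10)
  expect_equal(fit$chi2, 0, tolerance = 1e-18)

  # scale estimate invariant to rescaling sigma by a constant
  sig <- 0.05 * data$I
  f1 <- fit_scale_offset(model, data, sigma = sig)
  f2 <- fit_scale_offset(model, data, sigma = 10 * sig)
  expect_equal(f1$s, f2$s, tolerance = 1e-12)

  # grid-search oracle on a noisy case
  set.seed(97)
  noisy <- scattering_curve(q, 3.2 * I - 4 + rnorm(length(q), 0, 1))
  fit_n <- fit_scale_offset(model, noisy, sigma = rep(1, length(q)))
  ss <- seq(fit_n$s - 0.2, fit_n$s + 0.2, length.out = 81)
  cc <- seq(fit_n$c - 2, fit_n$c + 2, length.out = 81)
  obj <- outer(ss, cc, function(a, b) {
    sapply(seq_along(a), function(i) sum((a[i] * I + b[i] - noisy$I)^2))
  })
  best <- which(obj == min(obj), arr.ind = TRUE)
  expect_equal(fit_n$s, ss[best[1]], tolerance = 0.01)
  expect_equal(fit_n$c, cc[best[2]], tolerance = 0.1)
  expect_error(fit_scale_offset(scattering_curve(q, rep(1, length(q))),
                                data), "degenerate")
  td <- tidy(fit_n)
  expect_equal(td$term, c("scale", "offset"))
})

test_that("chi2 matches its definition and degenerates correctly", {
  q <- seq(0.05, 0.5, length.out = 20)
  I <- 50 * exp(-q * 3)
  model <- scattering_curve(q, I)
  data <- scattering_curve(q, I, sigma = 0.01 * I)
  expect_equal(chi2(model, data), 0)
  # residuals equal to sigma give reduced chi2 of 1
  data2 <- scattering_curve(q, I + 0.01 * I, sigma = 0.01 * I)
  expect_equal(chi2(model, data2), 1, tolerance = 1e-12)
  # hand-summed oracle on a random case
  set.seed(101)
  d3 <- scattering_curve(q, I + rnorm(20), sigma = runif(20, 0.5, 2))
  expect_equal(chi2(model, d3),
               sum(((I - d3$I) / d3$sigma)^2) / 20, tolerance = 1e-12)
  expect_equal(chi2(model, d3, reduced = FALSE),
               sum(((I - d3$I) / d3$sigma)^2), tolerance = 1e-12)
  # monotone non-increasing in pointwise sigma
  expect_lt(chi2(model, scattering_curve(q, d3$I, sigma = 2 * d3$sigma)),
            chi2(model, d3))
  expect_error(chi2(model, scattering_curve(q, I)), "uncertainties")
})

test_that("q-point selection is log-even inside the window", {
  q <- exp(seq(log(0.01), log(1.6), length.out = 200))
  cur <- scattering_curve(q, 1 / (1 + q^2))
  idx <- select_q_points(cur, 20)
  expect_equal(length(idx), 20)
  expect_true(all(q[idx] >= 0.03 - 1e-9 & q[idx] <= 0.6 + 1e-9))
  # hand-computed log grid: nearest data points to the even log targets
  targets <- exp(seq(log(0.03), log(0.6), length.out = 20))
  for (k in c(1, 10, 20)) {
    expect_lt(abs(log(q[idx[k]]) - log(targets[k])), 0.05)
  }
  expect_equal(length(select_q_points(cur, 1, window = c(0.05, 0.5))), 1)
  all_idx <- select_q_points(cur, length(q), window = range(q))
  expect_equal(all_idx, seq_along(q))
  expect_error(select_q_points(cur, 10, window = c(2, 3)), "outside")
})

test_that("effective-uncertainty bounds follow the fractional rules", {
  q <- seq(0.05, 0.5, length.out = 10)
  cur <- scattering_curve(q, 200 * exp(-q))
  u <- uncertainty_model(cur)
  expect_equal(u$sigma_max, 0.007 * cur$I)
  expect_equal(u$sigma_min, 0.4 * u$sigma_max)
  expect_equal(u$sigma, u$sigma_max)
  expect_true(all(u$sigma_min > 0))
  expect_error(uncertainty_model(scattering_curve(q, rep(-1, 10))),
               "positive")
})
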