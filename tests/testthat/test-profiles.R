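test_that("COM RDF of an ideal gas is flat and counts pairs correctly", {
  set.seed(41)
  # point "molecules": single-bead configurations (counterion beads)
  n <- 300; box <- 100
  bt <- bead_row <- bead_types()[bead_types()$name == "TQ5", ]
  beads <- tibble::tibble(
    molecule = 1:n, site = 1L, name = "NAI", type = "TQ5", role = "core",
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    virtual = FALSE, radius = bt$radius, charge = 0, mass = 36,
    xray_contrast = bt$xray_contrast, neutron_contrast = bt$neutron_contrast
  )
  cfg <- cg_configuration(beads, box, validate = FALSE)
  prof <- com_pair_rdf(cfg, r_max = 45, bin_width = 3)
  inner <- prof$g[prof$r > 10]
  expect_lt(max(abs(inner - 1)), 0.2)     # flat within sampling noise
  # counting identity: shell counts integrate to the observed pairs
  d <- stacksas:::min_image_dist(as.matrix(beads[, c("x", "y", "z")]),
                                 as.matrix(beads[, c("x", "y", "z")]), rep(box, 3))
  expect_equal(sum(prof$count), sum(d[upper.tri(d)] < 45))
  expect_error(com_pair_rdf(cfg, r_max = 80), "half")
})

test_that("COM RDF of generated stacks peaks at the stacking distance", {
  set.seed(43)
  cfgs <- lapply(1:5, function(s) place_stack(
    tpl_fixture, stack_spec(4, d_stack = 4.5, jitter_sigma = 0.2),
    box = 120, seed = s))
  prof <- com_pair_rdf(cg_ensemble(cfgs), r_max = 30, bin_width = 1)
  expect_equal(prof$r[which.max(prof$g)], 4.5, tolerance = 1)
})

test_that("closest-approach series matches an explicit O(n^2) scan", {
  rec <- ensemble_recipe(n_molecules = 8, seed = 17)
  ens <- build_ensemble(rec, tpl_fixture, n_configurations = 2)
  ser <- min_pair_distance_series(ens, "sulfonate")
  expect_equal(nrow(ser), 2)
  for (i in 1:2) {
    cfg <- ens$configurations[[i]]
    sel <- which(cfg$beads$role == "sulfonate")
    best <- Inf
    for (a in sel) for (b in sel) {
      if (cfg$beads$molecule[a] == cfg$beads$molecule[b]) next
      dx <- abs(cfg$beads$x[a] - cfg$beads$x[b])
      dy <- abs(cfg$beads$y[a] - cfg$beads$y[b])
      dz <- abs(cfg$beads$z[a] - cfg$beads$z[b])
      dx <- min(dx, cfg$box[1] - dx); dy <- min(dy, cfg$box[2] - dy)
      dz <- min(dz, cfg$box[3] - dz)
      best <- min(best, sqrt(dx^2 + dy^2 + dz^2))
    }
    expect_equal(ser$distance[i], best, tolerance = 1e-9)
  }
  # two beads at a known offset
  one <- place_stack(tpl_fixture, stack_spec(1), box = 200)
  two <- one
  two$beads$x <- two$beads$x + 25
  two$beads$molecule <- 2L
  cfg2 <- cg_configuration(dplyr::bind_rows(one$beads, two$beads), 200,
                           tpl_fixture)
  s2 <- min_pair_distance_series(cfg2, "C1")   # same site in both molecules
  expect_equal(s2$distance, 25, tolerance = 1e-9)
  expect_error(min_pair_distance_series(cfg2, "nosuchbead"), "empty")
})

test_that("angle and dihedral values agree with an independent oracle", {
  skip_if_not_installed("bio3d")
  # planar zigzag has dihedral 180, eclipsed has 0
  zig <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  expect_equal(abs(stacksas:::dihedral_angle(zig[1, , drop = FALSE],
                                             zig[2, , drop = FALSE],
                                             zig[3, , drop = FALSE],
                                             zig[4, , drop = FALSE])), 180)
  ecl <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(stacksas:::dihedral_angle(ecl[1, , drop = FALSE],
                                         ecl[2, , drop = FALSE],
                                         ecl[3, , drop = FALSE],
                                         ecl[4, , drop = FALSE]), 0)
  set.seed(47)
  for (i in 1:50) {
    p <- matrix(rnorm(12), 4, 3)
    mine <- stacksas:::dihedral_angle(p[1, , drop = FALSE],
                                      p[2, , drop = FALSE],
                                      p[3, , drop = FALSE],
                                      p[4, , drop = FALSE])
    oracle <- bio3d::torsion.xyz(as.vector(t(p)), atm.inc = 4)
    expect_equal(abs(mine), abs(oracle[!is.na(oracle)][1]), tolerance = 1e-4)
    # angles against the acos formula
    u <- p[1, ] - p[2, ]; v <- p[3, ] - p[2, ]
    ang_oracle <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
    mine_a <- stacksas:::bond_angle(p[1, , drop = FALSE],
                                    p[2, , drop = FALSE],
                                    p[3, , drop = FALSE])
    expect_equal(mine_a, ang_oracle, tolerance = 1e-8)
  }
})

test_that("internal-coordinate histograms normalize and flag degenerates", {
  rec <- ensemble_recipe(n_molecules = 10, seed = 23, jitter_sigma = 0.5)
  ens <- build_ensemble(rec, tpl_fixture, n_configurations = 2)
  h <- internal_coordinate_histograms(ens, bin_width = 10)
  expect_true(all(c("angle", "dihedral") %in% h$kind))
  for (tp in unique(h$tuple)) {
    sub <- h[h$tuple == tp, ]
    expect_equal(sum(sub$density) * 10, 1, tolerance = 1e-8)
  }
  expect_gte(attr(h, "n_excluded"), 0)
})
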