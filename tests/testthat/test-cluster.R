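test_that("constructed stacks and separated molecules cluster as built", {
  st <- place_stack(tpl_fixture, stack_spec(4), box = 200)
  a <- cluster_molecules(st, cutoff = 6)
  expect_equal(a$sizes$size, 4)

  # two molecules far apart stay singletons
  b1 <- stacksas:::mol_beads(tpl_fixture,
                             stacksas:::template_coords(tpl_fixture), 1L)
  xyz2 <- sweep(stacksas:::template_coords(tpl_fixture), 2, c(60, 0, 0), `+`)
  b2 <- stacksas:::mol_beads(tpl_fixture, xyz2, 2L)
  cfg <- cg_configuration(dplyr::bind_rows(b1, b2), 200, tpl_fixture)
  a2 <- cluster_molecules(cfg, cutoff = 6)
  expect_equal(nrow(a2$sizes), 2)
  expect_true(all(a2$sizes$size == 1))
})

test_that("single linkage equals brute-force graph components", {
  skip_if_not_installed("igraph")
  set.seed(71)
  for (trial in 1:100) {
    n_mol <- sample(4:12, 1)
    box <- 80
    beads <- purrr::map_dfr(seq_len(n_mol), function(m) {
      xyz <- stacksas:::rigid_transform(
        stacksas:::template_coords(tpl_fixture),
        stacksas:::random_rotation(), runif(3, 0, box))
      stacksas:::mol_beads(tpl_fixture, xyz, m)
    })
    cfg <- cg_configuration(beads, box, tpl_fixture, validate = FALSE)
    cutoff <- runif(1, 4, 12)
    a <- cluster_molecules(cfg, cutoff)
    # oracle: igraph components on the O(n^2) molecule contact graph
    adj <- stacksas:::contact_matrix(cfg, seq_len(n_mol), cutoff,
                                     "min-bead-distance")
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    oracle <- igraph::components(g)$membership
    # same partition up to label permutation
    expect_equal(length(unique(a$labels$cluster)), max(oracle))
    tab <- table(a$labels$cluster, oracle)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("clustering is cutoff-monotone and translation-invariant", {
  rec <- ensemble_recipe(n_molecules = 15, seed = 13)
  cfg <- build_ensemble(rec, tpl_fixture)$configurations[[1]]
  cuts <- c(3, 5, 7, 9, 12)
  n_clusters <- sapply(cuts, function(ct) nrow(cluster_molecules(cfg, ct)$sizes))
  expect_true(all(diff(n_clusters) <= 0))

  shifted <- cfg
  shifted$beads$x <- shifted$beads$x + cfg$box[1]       # one lattice vector
  shifted$beads$y <- shifted$beads$y - 2 * cfg$box[2]
  a0 <- cluster_molecules(cfg, 6); a1 <- cluster_molecules(shifted, 6)
  expect_equal(sort(a0$sizes$size), sort(a1$sizes$size))

  expect_error(cluster_molecules(cfg, min(cfg$box)), "half")
})

test_that("size distribution is mass-weighted and normalized", {
  # hand count for clusters {4, 4, 2}: p(4) = 8/10, p(2) = 2/10
  labels <- tibble::tibble(molecule = 1:10,
                           cluster = c(1, 1, 1, 1, 2, 2, 2, 2, 3, 3))
  sizes <- dplyr::count(labels, cluster, name = "size")
  a <- structure(list(labels = labels, sizes = sizes, cutoff = 6,
                      criterion = "min-bead-distance"),
                 class = "aggregate_assignment")
  d <- size_distribution(a)
  expect_equal(sum(d$p), 1, tolerance = 1e-12)
  expect_equal(d$p[d$size == 4], 0.8)
  expect_equal(d$p[d$size == 2], 0.2)
  expect_equal(monomer_fraction(d), 0)

  # cluster-centric variant: fraction of aggregates, not molecules
  dc <- size_distribution(a, weighting = "cluster")
  expect_equal(dc$p[dc$size == 4], 2 / 3)

  # all-monomer limit
  lab1 <- tibble::tibble(molecule = 1:5, cluster = 1:5)
  a1 <- structure(list(labels = lab1,
                       sizes = dplyr::count(lab1, cluster, name = "size"),
                       cutoff = 6, criterion = "min-bead-distance"),
                  class = "aggregate_assignment")
  d1 <- size_distribution(a1)
  expect_equal(monomer_fraction(d1), 1)
  expect_error(size_distribution(list()), "empty")
})

test_that("ensemble-weighted size distributions average per-frame results", {
  mk <- function(cl) {
    lab <- tibble::tibble(molecule = seq_along(cl), cluster = cl)
    structure(list(labels = lab,
                   sizes = dplyr::count(lab, cluster, name = "size"),
                   cutoff = 6, criterion = "min-bead-distance"),
              class = "aggregate_assignment")
  }
  a_mono <- mk(1:4)                  # p(1) = 1
  a_dimer <- mk(c(1, 1, 2, 2))       # p(2) = 1
  d <- size_distribution(list(a_mono, a_dimer), weights = c(0.25, 0.75))
  expect_equal(d$p[d$size == 1], 0.25)
  expect_equal(d$p[d$size == 2], 0.75)
})
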