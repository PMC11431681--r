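test_that("resettle assay is pure and a fixed point at original equilibria", {
  net <- small_net()
  cfg <- fast_config()
  rec <- settle(net, cfg)

  springs_before <- net$springs
  e1 <- resettle_energy(net, rec$positions, cfg)
  e2 <- resettle_energy(net, rec$positions, cfg)
  expect_identical(net$springs, springs_before)
  expect_identical(e1, e2)
  expect_equal(e1, rec$energy_current, tolerance = 1e-6)

  # settling cannot increase V: assayed energy never exceeds the energy of
  # the unrelaxed input configuration
  set.seed(2)
  p <- disturb(net, cfg)$positions
  expect_lte(resettle_energy(net, p, cfg), potential_energy(net, p))
})

test_that("PCA embedding is fitted on baselines and rigid-motion invariant", {
  net <- small_net()
  cfg <- fast_config()
  set.seed(5)
  recs <- lapply(1:8, function(i) settle(disturb(net, cfg), cfg))

  emb <- pca_embed(recs)
  expect_equal(dim(emb$scores), c(8, 2))
  expect_length(emb$explained, 2)

  # identical records embed at the origin
  same <- rep(recs[1], 4)
  emb0 <- pca_embed(same)
  expect_equal(max(abs(emb0$scores)), 0, tolerance = 1e-8)

  # rigid motion of the configurations leaves the embedding unchanged
  moved <- lapply(recs, function(r) {
    r$positions <- rigid_motion(r$positions, 1.1, c(5, 5))
    r$distance_vector <- distance_vector(net, r$positions)
    r
  })
  emb_m <- pca_embed(moved, fit_records = recs)
  expect_equal(emb_m$scores, emb$scores, tolerance = 1e-6)

  expect_error(pca_embed(recs[1:2]), "at least 3")
})

test_that("attractor clustering equals threshold-graph connected components", {
  net <- small_net()
  cfg <- fast_config()
  set.seed(6)
  recs <- lapply(1:12, function(i) settle(disturb(net, cfg), cfg))

  cl <- cluster_attractors(recs, tol = 0.01)
  expect_length(cl$labels, 12)
  expect_equal(sum(cl$counts), 12)

  # brute-force oracle: connected components of the pairwise threshold graph
  mat <- do.call(rbind, lapply(recs, `[[`, "distance_vector"))
  threshold <- 0.01 * sqrt(sum(colMeans(mat)^2))
  adj <- as.matrix(dist(mat)) < threshold
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  # same partition (up to label names)
  expect_equal(length(unique(cl$labels)), length(unique(comp)))
  expect_true(all(tapply(cl$labels, comp, function(x)
    length(unique(x))) == 1))

  # two well-separated configurations repeated 5x each -> two clusters of 5
  a <- recs[[1]]; b <- recs[[2]]
  cl2 <- cluster_attractors(c(rep(list(a), 5), rep(list(b), 5)))
  expect_equal(sort(cl2$counts), c(5L, 5L))
  expect_equal(length(cl2$counts), 2L)

  expect_equal(cluster_attractors(rep(list(a), 3))$counts, 3L)
})

test_that("log-energy standard score matches direct arithmetic and is scale-free", {
  # baseline log-energies {0, 1, 2} (mean 1, sd 1), learned log -2.4 -> 3.4
  base <- exp(c(0, 1, 2))
  expect_equal(std_score(base, exp(-2.4)), 3.4, tolerance = 1e-12)

  # learned at the baseline log-mean -> 0
  expect_equal(std_score(base, exp(1)), 0, tolerance = 1e-12)

  # invariance to multiplying all energies by a positive constant
  set.seed(8)
  b <- rlnorm(50, 3, 0.4)
  e <- 0.7
  for (c in c(1e-3, 1, 1e4))
    expect_equal(std_score(c * b, c * e), std_score(b, e),
                 tolerance = 1e-9)

  expect_error(std_score(rep(2, 5), 1), "variance")
  expect_error(std_score(numeric(0), 1), "nonempty")

  # linear scale for signed energies
  expect_equal(std_score(c(-1, 0, 1), -3, log = FALSE), 3)
})

test_that("an unlearned weak L-layer does not distort which optima are found", {
  tl <- generate_two_layer_problem(30, seed = 21)
  cfg <- sim_config(seed = 21)
  nc <- neutrality_check(tl$problem, tl$network, cfg, n_samples = 25)
  expect_length(nc$p_only, 25)
  expect_lt(nc$ks_statistic, 0.3)

  # sanity inversion: an L-layer 10x stiffer than P distorts strongly
  heavy <- tl$network
  heavy$springs$stiffness[heavy$springs$plastic] <- 10
  nc2 <- neutrality_check(tl$problem, heavy, cfg, n_samples = 25)
  expect_gt(nc2$ks_statistic, nc$ks_statistic)
  expect_gt(nc2$ks_statistic, 0.5)
})

test_that("binarised scoring respects the coupling energy and its symmetry", {
  sg <- generate_spinglass_problem(2, 1, coupling_values = 1, seed = 1)
  pos <- embed_spins(sg$network, c(1, 1))
  be <- binarised_energy(sg$problem, pos)
  expect_equal(be$spins, c(1L, 1L))
  expect_equal(be$energy, -1)

  # global spin flip leaves the energy unchanged
  sg2 <- generate_spinglass_problem(10, 0.5, seed = 9)
  s <- sample(c(-1L, 1L), 10, replace = TRUE)
  e1 <- binarised_energy(sg2$problem, embed_spins(sg2$network, s))$energy
  e2 <- binarised_energy(sg2$problem, embed_spins(sg2$network, -s))$energy
  expect_equal(e1, e2)

  plain <- two_mass_net()
  expect_error(binarised_energy(problem_instance(plain$springs),
                                plain$positions), "couplings")
})
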