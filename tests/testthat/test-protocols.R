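test_that("identical config and seed reproduce a run bit for bit", {
  net <- generate_random_network(12, 0.8, seed = 2)
  cfg <- sim_config(seed = 31, n_resets = 8)
  r1 <- run_scenario1(net, cfg)
  r2 <- run_scenario1(net, cfg)
  expect_identical(lapply(r1$records, `[[`, "distance_vector"),
                   lapply(r2$records, `[[`, "distance_vector"))
  expect_identical(r1$network_final$springs, r2$network_final$springs)
  expect_identical(r1$disturbances, r2$disturbances)
})

test_that("a checkpointed run resumes exactly where it stopped", {
  net <- generate_random_network(12, 0.8, seed = 2)
  cfg <- sim_config(seed = 31, n_resets = 10)
  full <- run_scenario1(net, cfg)

  half <- run_scenario1(net, cfg, n_resets = 5)
  resumed <- run_scenario1(net, cfg, n_resets = 5, resume = half)
  expect_identical(lapply(resumed$records, `[[`, "positions"),
                   lapply(full$records, `[[`, "positions"))
  expect_identical(resumed$network_final$springs,
                   full$network_final$springs)
  expect_identical(resumed$rng_state, full$rng_state)
})

test_that("a scenario-2 run checkpointed mid-loop resumes exactly", {
  tl <- generate_two_layer_problem(12, seed = 43)
  cfg <- sim_config(seed = 43, n_resets = 8, learning_rate = 0.05)
  full <- run_scenario2(tl$problem, tl$network, cfg)
  half <- run_scenario2(tl$problem, tl$network, cfg, n_resets = 4)
  resumed <- run_scenario2(tl$problem, tl$network, cfg, n_resets = 4,
                           resume = half)
  expect_identical(lapply(resumed$records, `[[`, "positions"),
                   lapply(full$records, `[[`, "positions"))
  expect_equal(resumed$energy_p, full$energy_p)
})

test_that("disabling learning yields the baseline distribution unchanged", {
  net <- generate_random_network(12, 0.8, seed = 3)
  cfg <- sim_config(seed = 32, n_resets = 6, learning_rate = 0)
  res <- run_scenario1(net, cfg)
  # springs never deformed
  expect_identical(res$network_final$springs, net$springs)
  # the resettle assay reproduces each record's own energy: with pristine
  # springs the "learned" and baseline systems are the same system
  sc <- scenario1_scores(res)
  expect_equal(sc$energy_original,
               vapply(res$records, `[[`, numeric(1), "energy_current"),
               tolerance = 1e-6)
  expect_equal(sc$baseline_energies, sc$energy_original,
               tolerance = 1e-6)

  # memory experiment with no learning: post == baseline start by start
  mem <- run_memory_experiment(small_net(), fast_config(learning_rate = 0),
                               n_starts = 5)
  expect_equal(lapply(mem$post, `[[`, "distance_vector"),
               lapply(mem$baseline, `[[`, "distance_vector"))
})

test_that("learning concentrates the visited-attractor distribution", {
  net <- generate_random_network(15, 0.9, seed = 6)
  cfg <- sim_config(seed = 33, n_resets = 60, learning_rate = 0.05)
  res <- run_scenario1(net, cfg)
  early <- attractor_entropy(res$records[1:20])
  late <- attractor_entropy(res$records[41:60])
  expect_lte(late, early + 1e-9)
})

test_that("scenario 2 melts the learning layer away to the problem springs", {
  tl <- generate_two_layer_problem(25, seed = 41)
  cfg <- sim_config(seed = 41, n_resets = 15, learning_rate = 0.05)
  res <- run_scenario2(tl$problem, tl$network, cfg)
  expect_true(res$final_phase$converged)
  expect_lt(res$energy_l, 1e-6 * res$energy_p)

  # the final record's P-energy is the energy of an equilibrium of the
  # problem layer alone (L exerts no force there)
  p_net <- spring_network(res$network_final$positions,
                          tl$problem$p_springs)
  # residual P-only force is bounded by the summed L stress budget, tiny
  # against the O(1) forces seen during settling
  expect_lt(max(sqrt(rowSums(net_forces(p_net)^2))), 1e-2)

  # no L layer: the loop reduces to independent sampling of P optima
  p_only <- generate_two_layer_problem(12, l_connect = 0, seed = 42)
  res0 <- run_scenario2(p_only$problem, p_only$network,
                        sim_config(seed = 42, n_resets = 4))
  expect_identical(res0$network_final$springs, p_only$network$springs)
  expect_equal(res0$final_phase$iterations, 0L)
})

test_that("run summaries and traces serialise the run faithfully", {
  net <- generate_random_network(10, 0.9, seed = 4)
  cfg <- sim_config(seed = 44, n_resets = 5)
  res <- run_scenario1(net, cfg)
  sc <- scenario1_scores(res)

  doc <- run_summary(res, assays = list(std_score = sc$score,
                                        n_clusters = 3L))
  expect_equal(doc$schema, "natind/1")
  expect_equal(doc$seed, 44L)
  expect_equal(doc$assays$std_score, sc$score)

  # identical runs give identical summaries modulo the timestamp
  doc2 <- run_summary(run_scenario1(net, cfg))
  doc$timestamp <- doc2$timestamp <- NULL
  doc$assays <- doc2$assays <- NULL
  expect_identical(doc, doc2)

  path <- tempfile(fileext = ".csv")
  res$records <- sc$records
  write_trace(res, path)
  df <- read.csv(path)
  expect_equal(nrow(df), 5)
  expect_equal(df$energy_original, sc$energy_original, tolerance = 1e-9)
})
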