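test_that("potential energy matches a per-spring recomputation", {
  # two masses, one spring: V = 1/2 * 10 * (11 - 10)^2 = 5
  expect_equal(potential_energy(two_mass_net(r0 = 11)), 5)

  # all springs at natural length -> V = 0
  at_rest <- two_mass_net(r0 = 10)
  expect_equal(potential_energy(at_rest), 0)

  # random network: independent vectorised oracle over springs
  net <- small_net()
  sp <- net$springs
  dx <- net$positions[sp$i, 1] - net$positions[sp$j, 1]
  dy <- net$positions[sp$i, 2] - net$positions[sp$j, 2]
  oracle <- sum(0.5 * sp$stiffness * (sqrt(dx^2 + dy^2) -
                                        sp$natural_length)^2)
  expect_equal(potential_energy(net), oracle, tolerance = 1e-12)
  expect_error(potential_energy(net, net$positions * NA), "finite")
})

test_that("forces obey Newton's third law and vanish at rest", {
  expect_equal(net_forces(two_mass_net(r0 = 10)),
               matrix(0, 2, 2))

  # stretched spring attracts, compressed repels
  f_str <- net_forces(two_mass_net(r0 = 12))
  expect_gt(f_str[1, 1], 0)   # mass 1 pulled toward mass 2 (+x)
  expect_lt(f_str[2, 1], 0)
  f_cmp <- net_forces(two_mass_net(r0 = 8))
  expect_lt(f_cmp[1, 1], 0)
  expect_gt(f_cmp[2, 1], 0)

  # conservation on a random network: total force ~ 0
  net <- small_net()
  f <- net_forces(net)
  typical <- max(abs(f))
  expect_lt(max(abs(colSums(f))), 1e-10 * typical)

  coincident <- spring_network(rbind(c(0, 0), c(0, 0)),
                               spring(1, 2, 1, 1))
  expect_error(net_forces(coincident), "degenerate")
})

test_that("settling reaches a critical point and is a fixed point there", {
  net <- small_net()
  cfg <- fast_config()
  rec <- settle(net, cfg)
  expect_true(rec$converged)
  expect_lt(rec$max_force,
            natind:::resolve_config(cfg, net)$equilibrium_tolerance)
  expect_gte(rec$energy_current, 0)

  # settling again from the equilibrium barely moves anything
  again <- settle(apply_record(net, rec), cfg)
  expect_lt(max(abs(again$positions - rec$positions)), 1e-6)
  expect_equal(length(rec$distance_vector), 15 * 14 / 2)
})

test_that("two-body overdamped relaxation follows the closed-form exponential", {
  # separation relaxes as l + (r0 - l) exp(-2 k t / gamma)
  r0 <- 1.5; k <- 1; l <- 1
  cfg <- sim_config(step_size = 1e-6, equilibrium_tolerance = 1e-12,
                    seed = 1)
  for (steps in c(4000, 8000, 16000, 28000, 40000)) {
    c2 <- cfg
    c2$max_settle_steps <- steps
    rec <- suppressWarnings(settle(two_mass_net(r0 = r0, k = k, l = l),
                                   c2, method = "euler"))
    sep <- abs(rec$positions[2, 1] - rec$positions[1, 1])
    expected <- l + (r0 - l) * exp(-2 * k * rec$sim_time / 1)
    expect_equal(sep, expected, tolerance = 1e-4)
  }
})

test_that("energy is non-increasing along every descent trajectory", {
  set.seed(42)
  cfg <- fast_config()
  for (s in 1:4) {
    net <- generate_random_network(12, 0.8, seed = s)
    net <- disturb(net, cfg)
    for (m in c("fire", "euler")) {
      rec <- settle(net, cfg, method = m, record_energy = TRUE)
      tr <- rec$energy_trace
      expect_true(all(diff(tr) <= 1e-12 * head(tr, -1) + 1e-300),
                  info = paste("method", m, "seed", s))
    }
    # inertial dynamics dissipate the total (elastic + kinetic) energy
    rec <- settle(net, cfg, method = "inertial", record_energy = TRUE)
    tr <- rec$energy_trace
    expect_true(all(diff(tr) <= 1e-6 * tr[1]))
  }
})

test_that("settling is equivariant under rigid motions of the start", {
  net <- small_net()
  cfg <- fast_config()
  set.seed(7)
  net <- disturb(net, cfg)
  base <- settle(net, cfg, method = "fire")

  moved <- net
  moved$positions <- rigid_motion(net$positions, theta = 0.7,
                                  shift = c(3, -2))
  rec <- settle(moved, cfg, method = "fire")
  expect_equal(rec$distance_vector, base$distance_vector,
               tolerance = 1e-6)
  expect_equal(rec$energy_current, base$energy_current, tolerance = 1e-9)
})

test_that("disturbances randomise positions but never touch springs", {
  net <- small_net()
  cfg <- fast_config()
  set.seed(3)
  d1 <- disturb(net, cfg)
  expect_identical(d1$springs, net$springs)

  # determinism under the RNG state
  set.seed(3)
  d2 <- disturb(net, cfg)
  expect_identical(d1$positions, d2$positions)

  # positions fall in the configured box
  cfg2 <- fast_config(box_size = 4)
  set.seed(1)
  d3 <- disturb(net, cfg2)
  expect_true(all(abs(d3$positions) <= 2))

  # a disturbed state is typically far above settled energies
  settled <- settle(net, cfg)
  set.seed(9)
  expect_gt(potential_energy(disturb(apply_record(net, settled), cfg)),
            settled$energy_current)
})

test_that("fixed anchor masses never move", {
  sg <- generate_spinglass_problem(6, 0.8, seed = 2)
  cfg <- sim_config(seed = 1, box_size = 3)
  anchors <- sg$network$positions[sg$network$fixed, ]
  set.seed(2)
  d <- disturb(sg$network, cfg)
  expect_identical(d$positions[d$fixed, ], anchors)
  rec <- settle(d, cfg)
  expect_identical(rec$positions[d$fixed, ], anchors)
})
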