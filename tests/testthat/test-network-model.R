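test_that("spring and network constructors enforce their invariants", {
  expect_error(spring(3, 3, 1, 10), "self-spring")
  expect_error(spring(1, 2, -1, 10), "stiffness")
  expect_error(spring(1, 2, 1, -2), "natural_length")
  expect_error(spring(1, 2, 1, 10, plastic = TRUE, creep_rate = 0),
               "creep_rate")

  sp <- rbind(spring(1, 2, 10, 10), spring(2, 3, 10, 10))
  net <- spring_network(matrix(rnorm(6), 3, 2), sp)
  expect_s3_class(net, "spring_network")
  expect_equal(net$n, 3)

  # one P and one L spring may share a pair, but not two in one layer
  mixed <- rbind(spring(1, 2, 10, 10),
                 spring(1, 2, 1, 10, plastic = TRUE))
  expect_silent(spring_network(matrix(rnorm(4), 2, 2), mixed))
  dup <- rbind(spring(1, 2, 10, 10), spring(2, 1, 5, 8))
  expect_error(spring_network(matrix(rnorm(4), 2, 2), dup), "duplicate")

  expect_error(spring_network(matrix(c(0, 0, Inf, 1), 2, 2),
                              spring(1, 2, 1, 1)), "finite")
})

test_that("random network generator matches its Bernoulli edge model", {
  # n = 2 at full connectivity: exactly the one possible spring
  n2 <- generate_random_network(2, 1.0, seed = 1)
  expect_equal(nrow(n2$springs), 1L)

  # Scenario-1 style small system
  net <- generate_random_network(15, 0.9, natural_length = 10,
                                 stiffness = 10, seed = 1)
  expect_equal(net$n, 15)
  expect_true(all(net$springs$stiffness == 10))
  expect_true(all(net$springs$natural_length == 10))
  expect_true(all(net$springs$plastic))

  # same seed reproduces the same draw
  again <- generate_random_network(15, 0.9, seed = 1)
  expect_identical(net$springs, again$springs)

  # Monte-Carlo edge count against the Binomial(C(20,2), 0.5) mean;
  # mean 95, sd of the 300-draw average = sqrt(190*0.25/300) ~ 0.40
  counts <- vapply(1:300, function(s)
    nrow(generate_random_network(20, 0.5, seed = s)$springs), numeric(1))
  expect_lt(abs(mean(counts) - 0.5 * choose(20, 2)), 4 * 0.40 + 1)

  expect_error(generate_random_network(1, 0.5), "n must be")
  expect_error(generate_random_network(10, 0), "connect_prob")
  # connectivity rejection: p too small to ever connect 30 masses
  expect_error(
    generate_random_network(30, 0.001, seed = 1, max_redraws = 5),
    "connected")
})

test_that("two-layer generator builds P and L layers as specified", {
  tl <- generate_two_layer_problem(40, p_connect = 0.5,
                                   p_length_range = c(0, 1),
                                   p_stiffness = 1, l_connect = 0.99,
                                   l_length_range = c(0, 1),
                                   l_stiffness = 0.1, seed = 3)
  sp <- tl$network$springs
  expect_true(all(!tl$problem$p_springs$plastic))
  expect_true(all(sp$stiffness[sp$plastic] == 0.1))
  expect_true(all(sp$natural_length >= 0 & sp$natural_length <= 1))
  # combined = P + L
  expect_equal(sum(!sp$plastic), nrow(tl$problem$p_springs))
  # P-layer count within binomial bounds: mean 390, sd ~ 14
  expect_lt(abs(sum(!sp$plastic) - 0.5 * choose(40, 2)), 5 * 14)

  # no L layer -> combined is exactly the P network
  p_only <- generate_two_layer_problem(10, l_connect = 0, seed = 4)
  expect_identical(p_only$network$springs, p_only$p_network$springs)

  expect_error(generate_two_layer_problem(10, l_stiffness = 2,
                                          p_stiffness = 1), "l_stiffness")
  expect_error(generate_two_layer_problem(10, p_length_range = c(1, 0)),
               "increasing")
})

test_that("spin-glass generator encodes the couplings faithfully", {
  # two-spin ferromagnet: ground state is equal spins at E = -1
  sg2 <- generate_spinglass_problem(2, 1, coupling_values = 1, seed = 1)
  gs2 <- enumerate_ground_state(sg2$problem$couplings, 2)
  expect_equal(gs2$energy, -1)
  expect_equal(gs2$spins[1], gs2$spins[2])

  # complete-graph ferromagnet: all spins equal
  sg20 <- generate_spinglass_problem(20, 1, coupling_values = 1, seed = 2)
  gs20 <- enumerate_ground_state(sg20$problem$couplings, 20)
  expect_true(all(gs20$spins == gs20$spins[1]))
  expect_equal(gs20$energy, -choose(20, 2))

  # structure of the embedding: 2 shared fixed anchors, bistable wells
  sg <- generate_spinglass_problem(12, 0.5, seed = 7)
  expect_equal(sum(sg$network$fixed), 2L)
  expect_true(all(!sg$problem$p_springs$plastic))
  # coupling springs: rest length 0 for J > 0 and 2 for J < 0
  cp <- sg$problem$couplings
  key <- paste(pmin(cp$i, cp$j), pmax(cp$i, cp$j))
  sp <- sg$problem$p_springs
  spk <- paste(sp$i, sp$j)
  rest <- sp$natural_length[match(key, spk)]
  expect_equal(rest, ifelse(cp$J > 0, 0, 2))
})

test_that("relaxing from the embedded ground state reproduces the exact optimum", {
  # the encoding's correctness test: the geometric ground state must be a
  # fixed point whose binarisation equals the enumerated optimum
  for (s in c(11, 12, 13)) {
    sg <- generate_spinglass_problem(12, 0.5, seed = s)
    gs <- enumerate_ground_state(sg$problem$couplings, 12)
    net <- sg$network
    net$positions <- embed_spins(net, gs$spins)
    rec <- settle(net, sim_config(seed = 1, box_size = 3), method = "fire")
    be <- binarised_energy(sg$problem, rec$positions)
    expect_equal(be$energy, gs$energy)
  }
})
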