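# small fixture builders shared across test files

# two masses joined by one spring, separated by r0 along the x axis
two_mass_net <- function(r0 = 11, k = 10, l = 10, plastic = FALSE,
                         creep_rate = k / 100) {
  spring_network(
    positions = rbind(c(0, 0), c(r0, 0)),
    springs = data.frame(i = 1L, j = 2L, stiffness = k, natural_length = l,
                         plastic = plastic, creep_rate = creep_rate))
}

# the small all-plastic system used throughout: N = 15, pc = 0.9,
# l0 = 10, k = 10
small_net <- function(seed = 5) {
  generate_random_network(15, 0.9, natural_length = 10, stiffness = 10,
                          seed = seed)
}

fast_config <- function(...) {
  args <- list(...)
  if (is.null(args$seed)) args$seed <- 1
  do.call(sim_config, args)
}

# random rigid motion of a position matrix
rigid_motion <- function(pos, theta, shift) {
  R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  sweep(pos %*% t(R), 2, -shift)
}
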