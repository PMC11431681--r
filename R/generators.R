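#' Generate a random geometric mass-spring network
#'
#' Connects each unordered pair of masses independently with probability
#' `connect_prob`; all springs share one stiffness, natural length, and
#' plasticity flag. Initial positions are drawn uniformly in a square of side
#' `sqrt(n) * natural_length` centred on the origin. Draws that leave the
#' graph disconnected are rejected and redrawn (a disconnected component
#' would not participate in the shared energy), up to `max_redraws` times.
#'
#' @param n number of masses, `>= 2`.
#' @param connect_prob per-pair connection probability in (0, 1].
#' @param natural_length,stiffness shared spring parameters.
#' @param plastic logical; generate deformable springs (default `TRUE`).
#' @param creep_rate creep rate constant for plastic springs.
#' @param seed optional integer seed (uses the current RNG state if `NULL`).
#' @param max_redraws bound on connectivity rejections.
#' @return a [spring_network()].
#' @export
generate_random_network <- function(n, connect_prob, natural_length = 10,
                                    stiffness = 10, plastic = TRUE,
                                    creep_rate = stiffness / 100,
                                    seed = NULL, max_redraws = 100) {
  if (n < 2) stop("n must be >= 2")
  if (connect_prob <= 0 || connect_prob > 1)
    stop("connect_prob must lie in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  for (try in seq_len(max_redraws)) {
    keep <- runif(nrow(pairs)) < connect_prob
    if (is_connected_pairs(n, pairs[keep, , drop = FALSE])) {
      box <- sqrt(n) * natural_length
      pos <- cbind(runif(n, -box / 2, box / 2), runif(n, -box / 2, box / 2))
      springs <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                            stiffness = stiffness,
                            natural_length = natural_length,
                            plastic = plastic,
                            creep_rate = if (plastic) creep_rate else NA_real_)
      return(spring_network(pos, springs))
    }
  }
  stop("failed to draw a connected graph in ", max_redraws, " attempts; ",
       "increase connect_prob or n")
}

# connectivity of an undirected graph given an edge matrix (2 columns)
is_connected_pairs <- function(n, edges) {
  if (n == 1) return(TRUE)
  if (nrow(edges) == 0) return(FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    v <- queue[1L]
    queue <- queue[-1L]
    nb <- adj[[v]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' An external problem instance
#'
#' Wraps the non-plastic problem layer, and for spin-glass problems the
#' coupling list together with the binarisation rule that reads spins off a
#' relaxed geometric configuration.
#'
#' @param p_springs data frame of non-plastic springs.
#' @param couplings optional data frame with columns `i, j, J` (variable
#'   indices and coupling weights).
#' @param binarisation optional list describing the spin read-out: element
#'   `var_idx` gives the mass index of each variable and `axis` the
#'   coordinate whose sign is the spin (ties broken to +1).
#' @return object of class `problem_instance`.
#' @export
problem_instance <- function(p_springs, couplings = NULL,
                             binarisation = NULL) {
  p_springs <- normalise_springs(p_springs)
  if (any(p_springs$plastic))
    stop("problem springs must be non-plastic")
  if (!is.null(couplings) && is.null(binarisation))
    stop("couplings require a binarisation rule")
  structure(list(p_springs = p_springs, couplings = couplings,
                 binarisation = binarisation),
            class = "problem_instance")
}

#' Generate a two-layer continuous problem (elastic P-layer + plastic L-layer)
#'
#' Builds the Scenario-2a style system: a sparse layer of perfectly elastic
#' problem springs (P) defining the energy landscape to be solved, overlaid
#' with a dense layer of much weaker plastic learning springs (L). Natural
#' lengths in each layer are drawn uniformly from the layer's range.
#'
#' @param n number of masses.
#' @param p_connect,p_length_range,p_stiffness P-layer connectivity, natural
#'   length interval `c(lo, hi)`, and stiffness.
#' @param l_connect,l_length_range,l_stiffness the same for the L-layer;
#'   `l_stiffness` must be smaller than `p_stiffness` (the learning layer is
#'   a weak field over the problem). `l_connect = 0` omits the layer.
#' @param creep_rate creep rate constant of the L-springs.
#' @param seed optional integer seed.
#' @return list with elements `problem` (a [problem_instance()] holding the
#'   P-layer), `network` (the combined two-layer [spring_network()]), and
#'   `p_network` (the P-layer alone, sharing the initial positions).
#' @export
generate_two_layer_problem <- function(n, p_connect = 0.5,
                                       p_length_range = c(0, 1),
                                       p_stiffness = 1,
                                       l_connect = 0.99,
                                       l_length_range = c(0, 1),
                                       l_stiffness = 0.1,
                                       creep_rate = l_stiffness / 100,
                                       seed = NULL) {
  stopifnot(length(p_length_range) == 2, length(l_length_range) == 2)
  if (diff(p_length_range) < 0 || diff(l_length_range) < 0)
    stop("length ranges must be increasing intervals")
  if (any(c(p_length_range, l_length_range) < 0))
    stop("natural lengths cannot be negative")
  if (l_connect > 0 && l_stiffness >= p_stiffness)
    stop("l_stiffness must be smaller than p_stiffness")
  if (!is.null(seed)) set.seed(seed)

  p_net <- generate_random_network(
    n, p_connect,
    natural_length = mean(p_length_range), stiffness = p_stiffness,
    plastic = FALSE)
  ps <- p_net$springs
  ps$natural_length <- runif(nrow(ps), p_length_range[1], p_length_range[2])
  p_net$springs <- ps

  springs <- ps
  if (l_connect > 0) {
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- runif(nrow(pairs)) < l_connect
    ls <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                     stiffness = l_stiffness,
                     natural_length = runif(sum(keep), l_length_range[1],
                                            l_length_range[2]),
                     plastic = TRUE, creep_rate = creep_rate)
    springs <- rbind(springs, ls)
  }
  combined <- spring_network(p_net$positions, springs)
  list(problem = problem_instance(ps), network = combined, p_network = p_net)
}

#' Generate a spin-glass (MaxCut) problem with a bistable spring embedding
#'
#' Draws a random +/-J spin glass: each unordered pair of variables carries a
#' coupling with probability `edge_prob`, with weight sampled uniformly from
#' `coupling_values`. The energy convention is `E = -sum_ij J_ij s_i s_j`
#' with spins in {-1, +1}; the ground state solves the MaxCut partition of
#' the coupling graph.
#'
#' The geometric embedding makes each variable a mass whose single-variable
#' energy is bistable with minima at x = -1 and x = +1: every variable is
#' tied by two strong non-plastic anchor springs to fixed pseudo-masses at
#' (0, h) and (0, -h), with natural length `sqrt(1 + h^2)` so both springs
#' are exactly unstressed only at (+/-1, 0). A coupling J is a non-plastic
#' spring between the two variables with natural length 0 for J > 0 (favours
#' the same side) and 2 for J < 0 (favours opposite sides), stiffness
#' `coupling_stiffness * |J|`. Spins are read off as the sign of the x
#' coordinate.
#'
#' @param n_vars number of spin variables, `>= 2`.
#' @param edge_prob probability that a pair is coupled.
#' @param coupling_values candidate weights, e.g. `c(-1, 1)`.
#' @param coupling_stiffness stiffness per unit |J|.
#' @param anchor_stiffness stiffness of the bistable anchor springs; the
#'   default scales with the expected coupled degree so the wells stay
#'   well-defined against the summed coupling forces.
#' @param h half-separation of the two anchor points.
#' @param seed optional integer seed.
#' @return list with `problem` (a [problem_instance()] carrying couplings
#'   and the binarisation rule) and `network` (the embedded P-layer network:
#'   variables + 2 fixed anchors, no learning layer yet; see
#'   [add_learning_layer()]).
#' @export
generate_spinglass_problem <- function(n_vars, edge_prob = 0.5,
                                       coupling_values = c(-1, 1),
                                       coupling_stiffness = 1,
                                       anchor_stiffness = NULL,
                                       h = 0.5, seed = NULL) {
  if (n_vars < 2) stop("n_vars must be >= 2")
  if (length(coupling_values) < 1) stop("coupling_values must be nonempty")
  if (!is.null(seed)) set.seed(seed)

  pairs <- which(upper.tri(matrix(0, n_vars, n_vars)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < edge_prob
  cp <- pairs[keep, , drop = FALSE]
  J <- sample(coupling_values, nrow(cp), replace = TRUE)
  couplings <- data.frame(i = cp[, 1], j = cp[, 2], J = J)

  if (is.null(anchor_stiffness))
    anchor_stiffness <-
      2 * max(1, n_vars * edge_prob) * coupling_stiffness *
      mean(abs(coupling_values))

  a1 <- n_vars + 1L   # fixed anchors, shared by all variables
  a2 <- n_vars + 2L
  l_anchor <- sqrt(1 + h^2)
  anchor_springs <- data.frame(
    i = rep(seq_len(n_vars), 2L),
    j = rep(c(a1, a2), each = n_vars),
    stiffness = anchor_stiffness, natural_length = l_anchor,
    plastic = FALSE, creep_rate = NA_real_)
  coupling_springs <- if (nrow(couplings)) data.frame(
    i = couplings$i, j = couplings$j,
    stiffness = coupling_stiffness * abs(couplings$J),
    natural_length = ifelse(couplings$J > 0, 0, 2),
    plastic = FALSE, creep_rate = NA_real_) else NULL
  p_springs <- rbind(anchor_springs, coupling_springs)

  # start every variable in a well chosen at random; anchors are immovable
  pos <- rbind(cbind(sample(c(-1, 1), n_vars, replace = TRUE),
                     rep(0, n_vars)),
               c(0, h), c(0, -h))
  fixed <- c(rep(FALSE, n_vars), TRUE, TRUE)
  net <- spring_network(pos, p_springs, fixed = fixed)
  binarisation <- list(var_idx = seq_len(n_vars), axis = 1L)
  list(problem = problem_instance(p_springs, couplings, binarisation),
       network = net)
}

#' Overlay a dense plastic learning layer on a problem network
#'
#' Adds weak plastic L-springs between random pairs of movable masses.
#' Natural lengths are drawn uniformly from `length_range`.
#'
#' @param network the problem-layer [spring_network()].
#' @param connect_prob per-pair connection probability.
#' @param length_range interval for the initial natural lengths.
#' @param stiffness L-spring stiffness; the default suits the spin-glass
#'   embedding (strong anchors dominate, couplings at stiffness ~1): weak
#'   enough that the pristine layer does not redefine the problem, strong
#'   enough that the learned layer can steer which well a variable falls
#'   into.
#' @param creep_rate creep rate constant.
#' @param seed optional integer seed.
#' @return the combined [spring_network()].
#' @export
add_learning_layer <- function(network, connect_prob = 0.99,
                               length_range = c(0, 2), stiffness = 0.8,
                               creep_rate = stiffness / 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- which(!network$fixed)
  pairs <- t(utils::combn(idx, 2))
  keep <- runif(nrow(pairs)) < connect_prob
  if (!any(keep)) return(network)
  ls <- data.frame(i = pairs[keep, 1], j = pairs[keep, 2],
                   stiffness = stiffness,
                   natural_length = runif(sum(keep), length_range[1],
                                          length_range[2]),
                   plastic = TRUE, creep_rate = creep_rate)
  spring_network(network$positions, rbind(network$springs, ls),
                 fixed = network$fixed)
}

#' Place variables at the embedded positions of a spin assignment
#'
#' @param network the spin-glass embedding network.
#' @param spins vector of -1/+1, one per variable (movable mass).
#' @return positions matrix with each variable at (`s_i`, 0).
#' @export
embed_spins <- function(network, spins) {
  idx <- which(!network$fixed)
  if (length(spins) != length(idx))
    stop("need one spin per variable")
  if (!all(spins %in% c(-1, 1))) stop("spins must be -1 or +1")
  pos <- network$positions
  pos[idx, 1] <- spins
  pos[idx, 2] <- 0
  pos
}

#' Exhaustive ground state of a small spin glass
#'
#' Enumerates all `2^n` spin assignments and returns a minimiser of
#' `E = -sum_ij J_ij s_i s_j`. Intended for instances with `n <= ~20`.
#'
#' @param couplings data frame with columns `i, j, J`.
#' @param n_vars number of variables.
#' @return list with `spins` (a minimising assignment, first variable fixed
#'   to +1 by the global spin-flip symmetry) and `energy`.
#' @export
enumerate_ground_state <- function(couplings, n_vars) {
  if (n_vars > 24) stop("enumeration is limited to n_vars <= 24")
  best_e <- Inf
  best_s <- NULL
  s <- integer(n_vars)
  ii <- couplings$i; jj <- couplings$j; J <- couplings$J
  for (code in 0:(2^(n_vars - 1) - 1)) {
    # fix s[1] = +1: energy is invariant under a global flip
    bits <- bitwAnd(bitwShiftR(code, 0:(n_vars - 2)), 1L)
    s <- c(1L, 1L - 2L * bits)
    e <- -sum(J * s[ii] * s[jj])
    if (e < best_e) {
      best_e <- e
      best_s <- s
    }
  }
  list(spins = best_s, energy = best_e)
}
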