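#' Construct a single spring
#'
#' A spring joins masses `i` and `j` with Hookean stiffness `stiffness` and
#' rest (natural) length `natural_length`. Plastic springs are viscoelastic
#' Maxwell elements: under sustained stress their natural length creeps
#' toward the current separation at rate `creep_rate * (r - l)`, where
#' `creep_rate` is the spring constant divided by the damping constant of the
#' series dashpot. Non-plastic ("problem") springs never deform.
#'
#' @param i,j 1-based mass indices, `i != j`.
#' @param stiffness spring constant, force per unit length, `> 0`.
#' @param natural_length rest length, `>= 0`.
#' @param plastic logical; `TRUE` for a deformable (L-) spring.
#' @param creep_rate creep rate constant (1/time); required `> 0` when
#'   `plastic`, ignored (stored as `NA`) otherwise.
#' @return one-row data frame with columns
#'   `i, j, stiffness, natural_length, plastic, creep_rate`.
#' @export
spring <- function(i, j, stiffness, natural_length, plastic = FALSE,
                   creep_rate = if (plastic) stiffness / 100 else NA_real_) {
  s <- data.frame(i = as.integer(i), j = as.integer(j),
                  stiffness = as.numeric(stiffness),
                  natural_length = as.numeric(natural_length),
                  plastic = as.logical(plastic),
                  creep_rate = as.numeric(creep_rate))
  validate_springs(s, n = max(s$i, s$j))
  s
}

#' Assemble a spring network
#'
#' The state of the dynamical system: `n` point masses in a 2D plane plus a
#' set of springs. Mass positions are the fast (state) variables; natural
#' lengths of plastic springs are the slow (structural) variables. Masses
#' flagged in `fixed` are immovable pseudo-masses (used as anchor points for
#' the spin-glass embedding); they are excluded from disturbances and from
#' the pairwise distance vector.
#'
#' @param positions numeric `n x 2` matrix of coordinates.
#' @param springs data frame of springs as produced by [spring()] (rows may
#'   be concatenated with `rbind`). At most one spring per unordered pair per
#'   layer; a plastic and a non-plastic spring may share a pair.
#' @param fixed logical vector of length `n`; `TRUE` marks an immovable
#'   pseudo-mass. Default: all movable.
#' @return object of class `spring_network`: a list with elements `n`,
#'   `positions`, `springs`, `fixed`.
#' @export
spring_network <- function(positions, springs, fixed = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2 || !is.numeric(positions))
    stop("positions must be a numeric n x 2 matrix")
  if (any(!is.finite(positions)))
    stop("all coordinates must be finite")
  n <- nrow(positions)
  if (is.null(fixed)) fixed <- rep(FALSE, n)
  if (length(fixed) != n) stop("fixed must have one entry per mass")
  springs <- normalise_springs(springs)
  validate_springs(springs, n)
  net <- list(n = n, positions = unname(positions), springs = springs,
              fixed = as.logical(fixed))
  class(net) <- "spring_network"
  net
}

# order each pair i < j and row order by (i, j, layer); makes duplicate
# detection and file round-trips canonical
normalise_springs <- function(springs) {
  springs <- as.data.frame(springs)
  need <- c("i", "j", "stiffness", "natural_length", "plastic", "creep_rate")
  if (!"creep_rate" %in% names(springs)) springs$creep_rate <- NA_real_
  if (!all(need %in% names(springs)))
    stop("springs must have columns ", paste(need, collapse = ", "))
  springs <- springs[need]
  flip <- springs$i > springs$j
  tmp <- springs$i[flip]
  springs$i[flip] <- springs$j[flip]
  springs$j[flip] <- tmp
  springs$i <- as.integer(springs$i)
  springs$j <- as.integer(springs$j)
  springs$plastic <- as.logical(springs$plastic)
  ord <- order(springs$plastic, springs$i, springs$j)
  springs <- springs[ord, , drop = FALSE]
  rownames(springs) <- NULL
  springs
}

validate_springs <- function(springs, n) {
  if (nrow(springs) == 0) return(invisible(springs))
  with(springs, {
    if (any(i == j)) stop("self-springs (i == j) are not allowed")
    if (any(i < 1 | j < 1 | i > n | j > n))
      stop("spring indices must lie in 1..", n)
    if (any(stiffness <= 0)) stop("stiffness must be > 0")
    if (any(natural_length < 0)) stop("natural_length must be >= 0")
    if (any(plastic & (!is.finite(creep_rate) | creep_rate <= 0)))
      stop("plastic springs need creep_rate > 0")
  })
  key <- paste(springs$i, springs$j, springs$plastic)
  if (anyDuplicated(key))
    stop("duplicate spring for a pair within one layer")
  invisible(springs)
}

#' @export
print.spring_network <- function(x, ...) {
  np <- sum(x$springs$plastic)
  cat("<spring_network> ", x$n, " masses (", sum(x$fixed), " fixed), ",
      nrow(x$springs), " springs (", np, " plastic, ",
      nrow(x$springs) - np, " elastic)\n", sep = "")
  invisible(x)
}

# current separation of every spring's endpoints
spring_separations <- function(net, positions = net$positions) {
  dx <- positions[net$springs$i, 1] - positions[net$springs$j, 1]
  dy <- positions[net$springs$i, 2] - positions[net$springs$j, 2]
  sqrt(dx * dx + dy * dy)
}

#' Pairwise distance vector of the movable masses
#'
#' The rigid-motion-invariant fingerprint of a configuration: all
#' `m (m - 1) / 2` pairwise Euclidean distances between movable masses, in
#' canonical [stats::dist()] order. Fixed anchor pseudo-masses are excluded.
#'
#' @param net a [spring_network()].
#' @param positions optional positions to use instead of `net$positions`.
#' @return numeric vector.
#' @export
distance_vector <- function(net, positions = net$positions) {
  as.numeric(dist(positions[!net$fixed, , drop = FALSE]))
}

#' Mean natural length and stiffness helpers
#' @noRd
mean_natural_length <- function(net) mean(net$springs$natural_length)

#' Simulation parameters
#'
#' Bundles the dynamics, disturbance, and learning parameters shared by all
#' protocols. Defaults that depend on the network (box size, force
#' tolerance) may be left `NULL` and are resolved against a network by the
#' functions that use them: `box_size` defaults to `sqrt(n) * mean natural
#' length` (keeping mass density roughly independent of `n`) and
#' `equilibrium_tolerance` to `1e-6 * mean stiffness * mean natural length`.
#'
#' @param damping global damping constant `gamma` (mobility of positions).
#' @param step_size base integration time step for the overdamped Euler
#'   scheme; the engine adapts the effective step between `step_size / 2^60`
#'   and `50 * step_size` subject to monotone energy descent.
#' @param equilibrium_tolerance max per-mass net force magnitude defining
#'   "settled", or `NULL` for the network-scaled default.
#' @param max_settle_steps cap on accepted integration steps per settle.
#' @param n_resets number of disturbances in a scenario run.
#' @param learning_rate per-equilibrium creep fraction `eta` in (0, 1), or
#'   0 to disable learning (the control condition): at
#'   each settled state every plastic spring moves this fraction of the way
#'   from its natural length to its current separation. The discrete
#'   surrogate for slow continuous creep between disturbances.
#' @param box_size side of the square (centred on the origin) from which
#'   disturbed positions are drawn, or `NULL` for the default.
#' @param mass per-mass inertia used by the `"inertial"` settle method
#'   (damped second-order dynamics); irrelevant to the overdamped methods.
#' @param settle_method default relaxation method used by [settle()] and the
#'   protocols: `"fire"` (fast minimisation), `"euler"` (overdamped
#'   first-order flow), `"inertial"` (lightly damped second-order dynamics;
#'   slower, but reproduces the basin statistics of the physical
#'   transients), or `"anneal"` (inertial transients, then FIRE polishing;
#'   the recommended protocol method).
#' @param anneal_time duration of the inertial phase of the `"anneal"`
#'   method, in time units; default six ring-down times `2 * mass /
#'   damping`, by when the transient amplitude has decayed below 1% and
#'   the basin is decided. Shorter annealing is cheaper and changes
#'   results only marginally.
#' @param seed integer RNG seed used by the protocols.
#' @return object of class `sim_config` (a list).
#' @export
sim_config <- function(damping = 1, step_size = 0.01,
                       equilibrium_tolerance = NULL,
                       max_settle_steps = 2e5, n_resets = 300,
                       learning_rate = 0.02, box_size = NULL, mass = 1,
                       settle_method = c("anneal", "fire", "euler",
                                         "inertial"),
                       anneal_time = NULL, seed = 1L) {
  settle_method <- match.arg(settle_method)
  if (is.null(anneal_time)) anneal_time <- 12 * mass / damping
  if (damping <= 0) stop("damping must be > 0")
  if (step_size <= 0) stop("step_size must be > 0")
  if (!is.null(equilibrium_tolerance) && equilibrium_tolerance <= 0)
    stop("equilibrium_tolerance must be > 0")
  if (learning_rate < 0 || learning_rate >= 1)
    stop("learning_rate must lie in [0, 1); 0 disables learning")
  if (mass <= 0) stop("mass must be > 0")
  cfg <- list(damping = damping, step_size = step_size,
              equilibrium_tolerance = equilibrium_tolerance,
              max_settle_steps = max_settle_steps, n_resets = n_resets,
              learning_rate = learning_rate, box_size = box_size,
              mass = mass, settle_method = settle_method,
              anneal_time = anneal_time, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# fill in network-dependent defaults
resolve_config <- function(config, net) {
  if (is.null(config$equilibrium_tolerance))
    config$equilibrium_tolerance <-
      1e-6 * mean(net$springs$stiffness) * mean_natural_length(net)
  if (is.null(config$box_size))
    config$box_size <- sqrt(net$n) * mean_natural_length(net)
  config
}
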