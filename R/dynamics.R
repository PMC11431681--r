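#' Elastic potential energy of a network
#'
#' `V = sum over springs of 1/2 * k * (r_ij - l_ij)^2`, where `r_ij` is the
#' current separation of the endpoints and `l_ij` the spring's natural
#' length. Zero exactly when every spring is at its natural length.
#'
#' @param net a [spring_network()].
#' @param positions optional positions overriding `net$positions`.
#' @return non-negative scalar energy.
#' @export
potential_energy <- function(net, positions = net$positions) {
  if (any(!is.finite(positions))) stop("non-finite positions")
  if (nrow(net$springs) == 0) return(0)
  energy_engine(positions, net$springs$i - 1L, net$springs$j - 1L,
                net$springs$stiffness, net$springs$natural_length)
}

#' Net elastic force on every mass
#'
#' The elastic contribution only: the force on mass `i` from spring `(i, j)`
#' is `-k (r_ij - l_ij)` along the unit vector from `j` to `i`, so stretched
#' springs attract their endpoints and compressed springs repel them.
#' Damping is not a force here; it enters the dynamics as the mobility in
#' [settle()]. Newton's third law holds pairwise, so the forces sum to zero
#' over all masses (fixed anchors included).
#'
#' @param net a [spring_network()].
#' @param positions optional positions overriding `net$positions`.
#' @return numeric `n x 2` matrix of force vectors.
#' @export
net_forces <- function(net, positions = net$positions) {
  if (any(!is.finite(positions))) stop("non-finite positions")
  r <- spring_separations(net, positions)
  if (any(r == 0))
    stop("degenerate geometry: connected masses are coincident (r = 0)")
  forces_engine(positions, net$springs$i - 1L, net$springs$j - 1L,
                net$springs$stiffness, net$springs$natural_length)
}

#' Relax a network to mechanical equilibrium
#'
#' Relaxes the mass positions until the largest per-mass force magnitude
#' drops below `equilibrium_tolerance` or `max_settle_steps` accepted steps
#' have been taken. Natural lengths are never modified here.
#'
#' Three integrators are available. `"fire"` (the default) is the fast
#' inertial relaxation engine standard in mechanical-network statics:
#' semi-implicit Euler with unit masses, velocity mixing toward the force
#' direction, and a restart whenever the power `F . v` turns negative; it
#' reaches a critical point of the energy an order of magnitude faster than
#' the physical flow on ill-conditioned networks. `"euler"` is explicit
#' Euler on the overdamped first-order flow `xdot_i = F_i / gamma` with an
#' adaptive step; its trajectory and reported `sim_time` are physically
#' meaningful. Both reject any step that would raise the energy (beyond
#' 1e-12 relative slack), so `V` is non-increasing at every accepted step.
#' `"inertial"` integrates the lightly damped second-order dynamics
#' `m vdot_i = F_i - gamma v_i`: positions transiently oscillate while the
#' total (elastic + kinetic) energy is dissipated, which anneals
#' trajectories preferentially into wide, deep basins; use it when the
#' basin statistics of the physical transient dynamics are what is being
#' measured. `"anneal"` runs the inertial dynamics for
#' `config$anneal_time` time units (default: six ring-down times
#' `2 m / gamma`, by when the transients have decayed and the basin is
#' decided) and then finishes with FIRE; it reproduces the basin statistics
#' of `"inertial"` at a fraction of the cost and is the recommended method
#' for the disturbance protocols.
#'
#' @param net a [spring_network()].
#' @param config a [sim_config()].
#' @param reset_index optional index stored in the returned record.
#' @param method `"fire"` (fast equilibrium finding), `"euler"` (faithful
#'   overdamped trajectory), `"inertial"` (damped second-order dynamics
#'   with mass `config$mass`), or `"anneal"` (inertial then FIRE);
#'   defaults to `config$settle_method`.
#' @param record_energy also return the per-step Lyapunov trace (`V`, or
#'   `V` + kinetic energy for `"inertial"`) as `energy_trace`.
#' @return an `equilibrium_record`: list with `reset_index`, `positions`,
#'   `distance_vector`, `energy_current`, `energy_original` (`NA` until
#'   filled by the resettle assay), `settle_steps`, `converged`,
#'   `max_force`, and `sim_time`. A run that hits the step cap is returned
#'   with `converged = FALSE` and a warning, not an error.
#' @export
settle <- function(net, config = sim_config(), reset_index = NA_integer_,
                   method = NULL, record_energy = FALSE) {
  if (is.null(method)) method <- config$settle_method %||% "fire"
  method <- match.arg(method, c("fire", "euler", "inertial", "anneal"))
  config <- resolve_config(config, net)
  out <- settle_engine(net$positions, net$springs$i - 1L, net$springs$j - 1L,
                       net$springs$stiffness, net$springs$natural_length,
                       !net$fixed, config$damping, config$step_size,
                       50 * config$step_size, config$equilibrium_tolerance,
                       config$max_settle_steps,
                       c(fire = 1L, euler = 0L, inertial = 2L,
                         anneal = 3L)[[method]],
                       config$mass %||% 1,
                       config$anneal_time %||%
                         (12 * (config$mass %||% 1) / config$damping),
                       record_energy)
  if (!out$converged)
    warning("settle stopped after ", format(out$steps, big.mark = ","),
            " steps with max force ", signif(out$max_force, 3),
            " > tolerance ", signif(config$equilibrium_tolerance, 3))
  rec <- list(reset_index = reset_index, positions = out$positions,
              energy_trace = if (record_energy) out$energy_trace,
              distance_vector = distance_vector(net, out$positions),
              energy_current = out$energy,
              energy_original = NA_real_,
              settle_steps = out$steps, converged = out$converged,
              max_force = out$max_force, sim_time = out$time)
  class(rec) <- "equilibrium_record"
  rec
}

#' @export
print.equilibrium_record <- function(x, ...) {
  cat("<equilibrium_record> reset ", x$reset_index, ": V = ",
      signif(x$energy_current, 6),
      if (!is.na(x$energy_original))
        paste0(", V_original = ", signif(x$energy_original, 6)),
      ", steps = ", x$settle_steps,
      if (!x$converged) " (NOT converged)", "\n", sep = "")
  invisible(x)
}

#' Copy a record's settled positions back into a network
#'
#' @param net a [spring_network()].
#' @param record an `equilibrium_record` from [settle()].
#' @return the network with updated positions.
#' @export
apply_record <- function(net, record) {
  net$positions <- record$positions
  net
}

#' Disturb the state of a network
#'
#' Redraws the positions of all movable masses i.i.d. uniformly in the
#' square of side `box_size` centred on the origin. Spring parameters --
#' including any learned natural lengths -- and fixed anchor pseudo-masses
#' are untouched: disturbances hit the state variables only. Uses R's
#' current RNG stream; seed it through the calling protocol.
#'
#' @param net a [spring_network()].
#' @param config a [sim_config()].
#' @return the disturbed network.
#' @export
disturb <- function(net, config = sim_config()) {
  config <- resolve_config(config, net)
  free <- !net$fixed
  m <- sum(free)
  half <- config$box_size / 2
  net$positions[free, ] <- cbind(runif(m, -half, half),
                                 runif(m, -half, half))
  net
}
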