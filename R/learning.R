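#' Creep rate of a plastic spring
#'
#' The Maxwell creep law: a plastic spring held at separation `r` changes
#' its natural length at rate `ldot = c (r - l)`, with `c = k / gamma_m` the
#' spring constant over the series-dashpot damping constant. Under tension
#' (separation exceeding the natural length) the spring lengthens, under
#' compression it shortens. This
#' equals `-dV/dl` up to the positive factor `1/gamma_m`, so creep is
#' gradient descent of the same elastic energy with respect to the
#' structural variables.
#'
#' @param spring one-row spring data frame (see [spring()]); must be
#'   plastic.
#' @param r current separation of its endpoints.
#' @return rate of change of the natural length (length/time).
#' @export
creep_rate <- function(spring, r) {
  if (!all(spring$plastic))
    stop("creep_rate is defined only for plastic springs")
  spring$creep_rate * (r - spring$natural_length)
}

#' Continuous-time creep trajectory at held separation
#'
#' Integrates the creep law for a single plastic spring whose endpoints are
#' held at fixed separation `r`, returning the natural length at the
#' requested times. (The closed form is
#' `l(t) = r + (l(0) - r) exp(-c t)`; this routine integrates the rate
#' numerically and is used to validate it.)
#'
#' @param spring one-row plastic spring data frame.
#' @param r held separation.
#' @param times increasing vector of times starting at 0.
#' @return numeric vector of natural lengths at `times`.
#' @export
creep_trajectory <- function(spring, r, times) {
  if (!all(spring$plastic)) stop("creep applies to plastic springs only")
  deriv <- function(t, y, parms) {
    sp <- spring
    sp$natural_length <- y[1]
    list(creep_rate(sp, r))
  }
  sol <- deSolve::ode(y = c(l = spring$natural_length), times = times,
                      func = deriv, parms = NULL,
                      rtol = 1e-10, atol = 1e-12)
  as.numeric(sol[, "l"])
}

#' Check the gradient identity behind creep
#'
#' Compares the analytic creep rate of every plastic spring against
#' `-(c / k) * dV/dl` evaluated by central differences, where `c` is the
#' spring's creep rate constant and `k` its stiffness. The two agree exactly
#' in exact arithmetic; the return value is the maximum relative
#' discrepancy across plastic springs.
#'
#' @param net a [spring_network()].
#' @param h central-difference step; the default scales with the natural
#'   length so truncation and round-off error stay balanced.
#' @return max absolute relative discrepancy (0 if no plastic springs).
#' @export
gradient_check <- function(net, h = NULL) {
  if (is.null(h)) h <- 1e-4 * (1 + mean(net$springs$natural_length))
  idx <- which(net$springs$plastic)
  if (!length(idx)) return(0)
  r <- spring_separations(net)
  worst <- 0
  for (s in idx) {
    sp <- net$springs[s, ]
    up <- net; up$springs$natural_length[s] <- sp$natural_length + h
    dn <- net; dn$springs$natural_length[s] <- sp$natural_length - h
    dVdl <- (potential_energy(up) - potential_energy(dn)) / (2 * h)
    analytic <- creep_rate(sp, r[s])
    numeric <- -(sp$creep_rate / sp$stiffness) * dVdl
    scale <- max(abs(analytic), abs(numeric), 1e-8)
    worst <- max(worst, abs(analytic - numeric) / scale)
  }
  worst
}

#' One per-equilibrium creep update
#'
#' The discrete surrogate for slow continuous creep between disturbances:
#' at a settled configuration every plastic spring moves the fraction
#' `learning_rate` of the way from its natural length to its current
#' separation, `l <- l + eta (r - l)`. Non-plastic springs are untouched.
#' Each updated spring's energy term shrinks by the factor
#' `(1 - eta)^2 < 1`, so the update strictly lowers the energy of the held
#' configuration unless all plastic springs are already unstressed.
#'
#' @param net a [spring_network()].
#' @param record optional `equilibrium_record` whose positions define the
#'   separations (defaults to the network's current positions, which must be
#'   settled for the update to be meaningful).
#' @param learning_rate creep fraction `eta` in (0, 1]; `eta = 1` sets
#'   every plastic spring exactly to its current separation (full
#'   accommodation).
#' @return the network with updated natural lengths.
#' @export
equilibrium_update <- function(net, record = NULL, learning_rate = 0.02) {
  if (learning_rate <= 0 || learning_rate > 1)
    stop("learning_rate must lie in (0, 1]")
  pos <- if (is.null(record)) net$positions else record$positions
  r <- spring_separations(net, pos)
  p <- net$springs$plastic
  net$springs$natural_length[p] <-
    net$springs$natural_length[p] +
    learning_rate * (r[p] - net$springs$natural_length[p])
  net
}

# largest stress magnitude k * |r - l| over plastic springs
max_plastic_stress <- function(net, positions = net$positions) {
  p <- net$springs$plastic
  if (!any(p)) return(0)
  r <- spring_separations(net, positions)
  max(abs(net$springs$stiffness[p] *
            (r[p] - net$springs$natural_length[p])))
}

#' Creep to near-completion at a held configuration
#'
#' Emulates leaving the system at rest for a long time: alternates one
#' per-equilibrium creep update with a (warm-started, hence cheap) resettle,
#' until the largest plastic-spring stress falls below `stress_frac` of its
#' initial value. Used by the memory experiment and by the final settling
#' phase of the two-layer protocols (with an absolute threshold there).
#'
#' @param net a [spring_network()] positioned at the configuration to hold.
#' @param config a [sim_config()].
#' @param stress_frac relative stress threshold (default 1%).
#' @param abs_stress optional absolute stress threshold overriding
#'   `stress_frac`.
#' @param max_iter iteration cap; exceeding it raises a warning.
#' @return list with `network` (deformed springs, resettled positions),
#'   `iterations`, and `converged`.
#' @export
creep_to_rest <- function(net, config = sim_config(), stress_frac = 0.01,
                          abs_stress = NULL, max_iter = 5000) {
  config <- resolve_config(config, net)
  target <- if (is.null(abs_stress))
    stress_frac * max_plastic_stress(net) else abs_stress
  it <- 0L
  while (max_plastic_stress(net) > target && it < max_iter) {
    net <- equilibrium_update(net, learning_rate = config$learning_rate)
    # accommodation is quasi-static: positions track the slowly moving
    # minimum, so relax with FIRE from the warm start
    rec <- settle(net, config, method = "fire")
    net <- apply_record(net, rec)
    it <- it + 1L
  }
  converged <- max_plastic_stress(net) <= target
  if (!converged)
    warning("plastic stress did not decay below the target in ",
            max_iter, " iterations")
  list(network = net, iterations = it, converged = converged)
}
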