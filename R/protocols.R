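#' Memory-formation experiment
#'
#' The basin-enlargement demonstration on a small all-plastic network:
#' (1) settle from `n_starts` random initial conditions with pristine
#' springs, giving the baseline distribution of equilibria; (2) hold the
#' first equilibrium sampled while the springs creep to near-completion;
#' (3) re-settle from the same `n_starts` initial conditions with the
#' deformed springs. With `learning_rate = 0` the creep step is skipped and
#' the post records repeat the baseline exactly.
#'
#' Settling uses the `"inertial"` method (lightly damped second-order
#' dynamics): the claim under test is about the basins of the physical
#' transient dynamics, whose ringing anneals trajectories into wide deep
#' basins, and the deformed configuration's basin is measured under those
#' dynamics.
#'
#' @param network an all-plastic [spring_network()].
#' @param config a [sim_config()]; `seed` fixes the initial conditions.
#' @param n_starts number of random initial conditions.
#' @param stress_frac creep completion threshold (fraction of the held
#'   configuration's initial plastic stress).
#' @param method settle method for the basin assays (default `"inertial"`).
#' @return list with `baseline` (records), `held` (the record the system
#'   rested at), `post` (records after deformation), `starts` (the shared
#'   initial positions), and `deformed_network`.
#' @export
run_memory_experiment <- function(network, config = sim_config(),
                                  n_starts = 1000, stress_frac = 0.01,
                                  method = "inertial") {
  config <- resolve_config(config, network)
  set.seed(config$seed)
  starts <- replicate(n_starts, disturb(network, config)$positions,
                      simplify = FALSE)
  settle_from <- function(net, p, k) {
    net$positions <- p
    settle(net, config, reset_index = k, method = method)
  }
  baseline <- lapply(seq_along(starts), function(k)
    settle_from(network, starts[[k]], k))
  held <- baseline[[1L]]

  deformed <- network
  if (config$learning_rate > 0) {
    deformed <- apply_record(deformed, held)
    deformed <- creep_to_rest(deformed, config,
                              stress_frac = stress_frac)$network
  }
  post <- lapply(seq_along(starts), function(k)
    settle_from(deformed, starts[[k]], k))
  list(baseline = baseline, held = held, post = post, starts = starts,
       deformed_network = deformed)
}

# the shared disturb -> settle -> record -> creep loop
run_disturbance_loop <- function(net, config, n_resets) {
  records <- vector("list", n_resets)
  disturbances <- vector("list", n_resets)
  for (t in seq_len(n_resets)) {
    net <- disturb(net, config)
    disturbances[[t]] <- net$positions
    rec <- settle(net, config, reset_index = t)
    net <- apply_record(net, rec)
    rec$max_plastic_stress <- max_plastic_stress(net)
    if (config$learning_rate > 0)
      net <- equilibrium_update(net, rec, config$learning_rate)
    records[[t]] <- rec
  }
  list(network = net, records = records, disturbances = disturbances)
}

#' Scenario 1: self-optimisation of an all-plastic network
#'
#' Runs `n_resets` cycles of disturb, settle, record, and one
#' per-equilibrium creep update. Reproducible from `config$seed`; a run can
#' be stopped and resumed exactly via `resume` (the result carries the
#' spring state and the RNG state).
#'
#' @param network an all-plastic [spring_network()].
#' @param config a [sim_config()].
#' @param n_resets number of disturbances (defaults to `config$n_resets`).
#' @param resume a previous result to continue from; its config/seed are
#'   reused and `n_resets` counts the additional disturbances.
#' @return object of class `natind_run`: list with `scenario`, `records`,
#'   `disturbances`, `network_initial` (pristine springs),
#'   `network_final`, `config`, and the final RNG state.
#' @export
run_scenario1 <- function(network, config = sim_config(),
                          n_resets = config$n_resets, resume = NULL) {
  if (is.null(resume)) {
    config <- resolve_config(config, network)
    set.seed(config$seed)
    pristine <- network
    net <- network
    records <- list()
    disturbances <- list()
  } else {
    config <- resume$config
    assign(".Random.seed", resume$rng_state, envir = globalenv())
    pristine <- resume$network_initial
    net <- resume$network_final
    records <- resume$records
    disturbances <- resume$disturbances
  }
  out <- run_disturbance_loop(net, config, n_resets)
  done <- length(records)
  new_records <- lapply(seq_along(out$records), function(k) {
    r <- out$records[[k]]
    r$reset_index <- done + k
    r
  })
  res <- list(scenario = "s1",
              records = c(records, new_records),
              disturbances = c(disturbances, out$disturbances),
              network_initial = pristine,
              network_final = out$network,
              config = config,
              rng_state = get(".Random.seed", envir = globalenv()))
  class(res) <- "natind_run"
  res
}

#' Scenario 2: solving an external problem held in non-plastic springs
#'
#' Same disturbance loop as Scenario 1 on the combined network (elastic
#' problem springs plus plastic learning springs), followed by a final
#' settling phase that alternates settling and creep updates until every
#' learning spring's stress magnitude falls below
#' `1e-3 * mean L stiffness * mean natural length`, so the learning layer
#' exerts essentially no force and the problem springs alone fix the final
#' configuration.
#'
#' @param problem a [problem_instance()] holding the pristine P-layer.
#' @param combined the combined P+L [spring_network()].
#' @param config a [sim_config()].
#' @param n_resets number of disturbances.
#' @param resume a previous result to continue from (its disturbance loop
#'   is extended by `n_resets` and the final settling phase is redone).
#' @return object of class `natind_run` with the fields of [run_scenario1()]
#'   plus `final_record`, `energy_p` (problem-layer energy of the final
#'   configuration), `energy_l` (residual learning-layer energy), and
#'   `final_phase` (iterations and convergence of the settle-out).
#' @export
run_scenario2 <- function(problem, combined, config = sim_config(),
                          n_resets = config$n_resets, resume = NULL) {
  if (is.null(resume)) {
    config <- resolve_config(config, combined)
    set.seed(config$seed)
    prev_records <- list()
    prev_disturbances <- list()
    loop_net <- combined
  } else {
    config <- resume$config
    assign(".Random.seed", resume$loop_rng_state, envir = globalenv())
    prev_records <- resume$loop_records
    prev_disturbances <- resume$disturbances
    combined <- resume$network_initial
    loop_net <- resume$loop_network
  }
  out <- run_disturbance_loop(loop_net, config, n_resets)
  done <- length(prev_records)
  out$records <- lapply(seq_along(out$records), function(k) {
    r <- out$records[[k]]
    r$reset_index <- done + k
    r
  })
  out$records <- c(prev_records, out$records)
  out$disturbances <- c(prev_disturbances, out$disturbances)

  loop_rng <- get(".Random.seed", envir = globalenv())
  lmask <- out$network$springs$plastic
  final_phase <- list(iterations = 0L, converged = TRUE)
  net <- out$network
  if (any(lmask) && config$learning_rate > 0) {
    abs_stress <- 1e-3 * mean(net$springs$stiffness[lmask]) *
      mean_natural_length(combined)
    cr <- creep_to_rest(net, config, abs_stress = abs_stress)
    net <- cr$network
    final_phase <- list(iterations = cr$iterations,
                        converged = cr$converged)
  }
  final <- settle(net, config, reset_index = n_resets + 1L)
  net <- apply_record(net, final)
  p_net <- spring_network(net$positions, problem$p_springs,
                          fixed = net$fixed)
  energy_p <- potential_energy(p_net)
  energy_l <- final$energy_current - energy_p

  res <- list(scenario = "s2",
              records = out$records, disturbances = out$disturbances,
              network_initial = combined, network_final = net,
              loop_network = out$network, loop_records = out$records,
              loop_rng_state = loop_rng,
              config = config, rng_state = get(".Random.seed",
                                               envir = globalenv()),
              final_record = final, energy_p = energy_p,
              energy_l = energy_l, final_phase = final_phase)
  class(res) <- "natind_run"
  res
}

#' @export
print.natind_run <- function(x, ...) {
  cat("<natind_run> scenario ", x$scenario, ", ", length(x$records),
      " resets, seed ", x$config$seed, "\n", sep = "")
  if (!is.null(x$energy_p))
    cat("  final problem-layer energy: ", signif(x$energy_p, 6),
        " (residual L energy ", signif(x$energy_l, 3), ")\n", sep = "")
  invisible(x)
}

#' Score a Scenario 1 run against its unlearned baseline
#'
#' Fills each record's `energy_original` via the resettle assay (settling a
#' pristine copy of the original springs from the learned configuration),
#' replays the identical disturbances against the pristine springs to get
#' the baseline energy sample, and computes the log-energy standard score
#' of the minimum late-run original-system energy.
#'
#' @param result a `natind_run` from [run_scenario1()].
#' @param late_frac fraction of the run counted as "late" when taking the
#'   learned minimum (default: final quarter).
#' @return list with `energy_original` (per reset), `baseline_energies`
#'   (per identical disturbance), `learned_min`, `score`, and `records`
#'   (with `energy_original` filled in).
#' @export
scenario1_scores <- function(result, late_frac = 0.25) {
  config <- result$config
  pristine <- result$network_initial
  records <- lapply(result$records, function(r) {
    r$energy_original <- resettle_energy(pristine, r$positions, config)
    r
  })
  eo <- vapply(records, `[[`, numeric(1), "energy_original")
  baseline <- vapply(result$disturbances, function(p)
    resettle_energy(pristine, p, config), numeric(1))
  n <- length(eo)
  late <- seq.int(max(1L, ceiling((1 - late_frac) * n) + 1L), n)
  learned_min <- min(eo[late])
  list(energy_original = eo, baseline_energies = baseline,
       learned_min = learned_min,
       score = std_score(baseline, learned_min),
       records = records)
}

#' Score a Scenario 2 run against its unlearned baseline
#'
#' Replays the run's disturbances against the problem layer alone and
#' scores the final problem-layer energy (Scenario 2a, log scale) or the
#' binarised coupling energy (Scenario 2b, linear scale) against that
#' baseline sample.
#'
#' @param result a `natind_run` from [run_scenario2()].
#' @param problem the [problem_instance()] the run solved.
#' @param binarise score binarised coupling energies (Scenario 2b) instead
#'   of problem-layer elastic energies (Scenario 2a).
#' @return list with `baseline_energies`, `learned_energy`, `score`, and
#'   for `binarise = TRUE` also `spins` and `baseline_spins`.
#' @export
scenario2_scores <- function(result, problem, binarise = FALSE) {
  config <- result$config
  combined <- result$network_initial
  p_net <- spring_network(combined$positions, problem$p_springs,
                          fixed = combined$fixed)
  base_recs <- lapply(result$disturbances, function(p) {
    settle(spring_network(p, problem$p_springs, fixed = combined$fixed),
           config)
  })
  if (binarise) {
    base_bin <- lapply(base_recs, function(r)
      binarised_energy(problem, r$positions))
    baseline <- vapply(base_bin, `[[`, numeric(1), "energy")
    learned <- binarised_energy(problem, result$network_final$positions)
    list(baseline_energies = baseline, learned_energy = learned$energy,
         score = std_score(baseline, learned$energy, log = FALSE),
         spins = learned$spins,
         baseline_spins = lapply(base_bin, `[[`, "spins"))
  } else {
    baseline <- vapply(base_recs, `[[`, numeric(1), "energy_current")
    list(baseline_energies = baseline, learned_energy = result$energy_p,
         score = std_score(baseline, result$energy_p))
  }
}

#' Entropy of the visited-attractor distribution
#'
#' Clusters the records into attractors and returns the Shannon entropy (in
#' nats) of the visit distribution. The positive-feedback signature of
#' natural induction is that this entropy shrinks over the course of a run.
#'
#' @param records list of `equilibrium_record`s.
#' @param tol clustering tolerance passed to [cluster_attractors()].
#' @return scalar entropy.
#' @export
attractor_entropy <- function(records, tol = 0.01) {
  cl <- cluster_attractors(records, tol)
  p <- cl$counts / sum(cl$counts)
  -sum(p * base::log(p))
}
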