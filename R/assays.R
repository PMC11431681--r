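#' Resettle assay: energy of a configuration in the original system
#'
#' Evaluates a (possibly learned) configuration against the pristine,
#' pre-learning springs: a copy of the original network is placed at
#' `positions` and allowed to settle, and the settled energy under the
#' original natural lengths is returned. This finds which attractor of the
#' original system the configuration belongs to. The assay is pure: no
#' learning happens and none of its inputs are mutated.
#'
#' @param original_net a [spring_network()] carrying the pristine springs.
#' @param positions configuration to assay.
#' @param config a [sim_config()].
#' @return settled energy under the original springs (`V_o`).
#' @export
resettle_energy <- function(original_net, positions, config = sim_config()) {
  net <- original_net
  net$positions <- as.matrix(positions)
  rec <- settle(net, config)
  rec$energy_current
}

#' PCA embedding of equilibrium records
#'
#' Fits a principal-component transform on the pairwise-distance vectors of
#' `fit_records` (typically the baseline sample) and projects `records` onto
#' the first two components. Because the underlying coordinates are pairwise
#' distances, the embedding is invariant to rigid motions of the
#' configurations.
#'
#' @param records list of `equilibrium_record`s to project.
#' @param fit_records records used to fit the transform (default:
#'   `records`); at least 3 required.
#' @return list with `scores` (n x 2 matrix), `transform` (the fitted
#'   `prcomp` object), and `explained` (variance fractions of the first two
#'   components).
#' @export
pca_embed <- function(records, fit_records = records) {
  if (length(fit_records) < 3)
    stop("need at least 3 records to fit the embedding")
  fit_mat <- do.call(rbind, lapply(fit_records, `[[`, "distance_vector"))
  pc <- prcomp(fit_mat, center = TRUE, scale. = FALSE)
  mat <- do.call(rbind, lapply(records, `[[`, "distance_vector"))
  scores <- scale(mat, center = pc$center, scale = FALSE) %*%
    pc$rotation[, 1:2, drop = FALSE]
  tot <- sum(pc$sdev^2)
  explained <- if (tot > 0) pc$sdev[1:2]^2 / tot else c(0, 0)
  list(scores = unname(scores), transform = pc, explained = explained)
}

#' Cluster settled configurations into attractors
#'
#' Single-linkage agglomeration of the records' distance vectors, cut at
#' `tol` times the norm of the mean distance vector: two records share an
#' attractor when a chain of records links them at Euclidean distance below
#' the threshold. Equivalent to connected components of the threshold
#' graph. Cluster labels are deterministic given the input order (numbered
#' by first occurrence).
#'
#' @param records nonempty list of `equilibrium_record`s.
#' @param tol relative distance threshold (default 1%).
#' @return list with `labels` (integer per record) and `counts` (visits per
#'   cluster, in label order).
#' @export
cluster_attractors <- function(records, tol = 0.01) {
  if (!length(records)) stop("records must be nonempty")
  mat <- do.call(rbind, lapply(records, `[[`, "distance_vector"))
  if (nrow(mat) == 1) return(list(labels = 1L, counts = 1L))
  threshold <- tol * sqrt(sum(colMeans(mat)^2))
  hc <- hclust(dist(mat), method = "single")
  raw <- cutree(hc, h = threshold)
  labels <- match(raw, unique(raw))  # renumber by first occurrence
  list(labels = labels, counts = as.integer(table(labels)[as.character(
    seq_len(max(labels)))]))
}

#' Log-energy standard score of a learned energy against a baseline
#'
#' How unlikely the learned energy would be under the unlearned system:
#' `(mean(log E_baseline) - log(E_learned)) / sd(log E_baseline)`, positive
#' when the learned energy lies below the baseline mean. Computed on the
#' log scale by default (equilibrium energies are closer to log-normal);
#' energies are floored at `floor` before taking logs. Set `log = FALSE`
#' for quantities already on a natural linear scale (e.g. binarised
#' spin-glass energies, which may be negative).
#'
#' @param baseline_energies nonempty numeric vector.
#' @param learned_min_energy scalar learned energy.
#' @param log use the log scale (default `TRUE`).
#' @param floor lower clamp applied before `log`.
#' @return the score, in baseline standard deviations.
#' @export
std_score <- function(baseline_energies, learned_min_energy, log = TRUE,
                      floor = 1e-12) {
  if (!length(baseline_energies)) stop("baseline_energies must be nonempty")
  if (log) {
    baseline_energies <- base::log(pmax(baseline_energies, floor))
    learned_min_energy <- base::log(max(learned_min_energy, floor))
  }
  s <- sd(baseline_energies)
  if (!is.finite(s) || s == 0)
    stop("baseline energies have zero variance; the score is undefined")
  (mean(baseline_energies) - learned_min_energy) / s
}

#' Neutrality of an unlearned learning layer
#'
#' Checks that adding a pristine (unlearned) L-layer does not distort which
#' problem-layer optima are found. From `n_samples` identical random starts
#' it collects (A) settle energies of the problem layer alone, and (B)
#' energies obtained by settling the combined system, deleting the L-layer,
#' resettling, and reading the problem-layer energy. Reports both samples
#' and their Kolmogorov-Smirnov statistic.
#'
#' @param problem a [problem_instance()].
#' @param combined the combined P+L [spring_network()] (pristine L-layer).
#' @param config a [sim_config()]; its seed fixes the starts.
#' @param n_samples number of random starts.
#' @return list with `p_only`, `resettled` (energy vectors) and
#'   `ks_statistic`.
#' @export
neutrality_check <- function(problem, combined, config = sim_config(),
                             n_samples = 50) {
  p_net <- spring_network(combined$positions, problem$p_springs,
                          fixed = combined$fixed)
  config <- resolve_config(config, combined)
  set.seed(config$seed)
  starts <- replicate(n_samples, disturb(combined, config)$positions,
                      simplify = FALSE)
  a <- vapply(starts, function(p) {
    settle(spring_network(p, problem$p_springs, fixed = combined$fixed),
           config)$energy_current
  }, numeric(1))
  b <- vapply(starts, function(p) {
    full <- combined
    full$positions <- p
    rec <- settle(full, config)
    resettle_energy(p_net, rec$positions, config)
  }, numeric(1))
  ks <- suppressWarnings(ks.test(a, b)$statistic)
  list(p_only = a, resettled = b, ks_statistic = unname(ks))
}

#' Binarise a configuration and score it against the couplings
#'
#' Reads a spin vector off a relaxed configuration of a spin-glass
#' embedding (the sign of each variable's coordinate on the binarisation
#' axis, ties broken to +1) and returns the coupling energy
#' `E = -sum_ij J_ij s_i s_j`.
#'
#' @param problem a [problem_instance()] with couplings and binarisation.
#' @param positions configuration to read.
#' @return list with `spins` and `energy`.
#' @export
binarised_energy <- function(problem, positions) {
  if (is.null(problem$couplings) || is.null(problem$binarisation))
    stop("problem has no couplings/binarisation")
  b <- problem$binarisation
  x <- positions[b$var_idx, b$axis]
  spins <- ifelse(x >= 0, 1L, -1L)
  e <- -sum(problem$couplings$J * spins[problem$couplings$i] *
              spins[problem$couplings$j])
  list(spins = spins, energy = e)
}

#' Fraction of records that converged to a reference configuration
#'
#' A record matches when its distance vector lies within `tol` relative
#' Euclidean distance of the reference record's. Rigid-motion invariant.
#'
#' @param records list of `equilibrium_record`s.
#' @param reference the reference `equilibrium_record`.
#' @param tol relative tolerance (default 1%).
#' @return fraction between 0 and 1.
#' @export
convergence_fraction <- function(records, reference, tol = 0.01) {
  ref <- reference$distance_vector
  nref <- sqrt(sum(ref^2))
  hits <- vapply(records, function(r) {
    sqrt(sum((r$distance_vector - ref)^2)) < tol * nref
  }, logical(1))
  mean(hits)
}
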