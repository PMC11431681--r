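#' Read / write spring networks as plain-text edge lists
#'
#' The file format is whitespace-separated, one spring per line:
#' `i j stiffness natural_length layer [creep_rate]` with 0-based mass
#' indices and `layer` either `P` (elastic) or `L` (plastic). The
#' `creep_rate` column is written for L-springs and optional on input
#' (default: stiffness / 100). Lines starting with `#` are comments;
#' `write_edge_list()` records mass positions and fixed flags in
#' `# pos i x y [fixed]` comment lines, which `read_edge_list()` recognises.
#' Files without position lines get a deterministic circular layout.
#'
#' Round trip is exact: reading a written file reproduces indices,
#' stiffnesses, natural lengths, plasticity flags, creep rates, positions
#' and fixed flags.
#'
#' @param path file path.
#' @param n_masses optional mass count (default: inferred from the largest
#'   index seen in springs and position lines).
#' @return `read_edge_list()`: a [spring_network()].
#' @export
read_edge_list <- function(path, n_masses = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  springs <- list()
  pos_lines <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "") next
    if (startsWith(line, "#")) {
      f <- strsplit(sub("^#\\s*", "", line), "\\s+")[[1]]
      if (length(f) >= 4 && f[1] == "pos")
        pos_lines[[length(pos_lines) + 1]] <-
          list(i = as.integer(f[2]) + 1L, x = as.numeric(f[3]),
               y = as.numeric(f[4]),
               fixed = length(f) >= 5 && f[5] == "fixed")
      next
    }
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) < 5 || length(f) > 6)
      stop("line ", ln, ": expected 'i j stiffness natural_length layer ",
           "[creep_rate]'")
    i <- suppressWarnings(as.integer(f[1]))
    j <- suppressWarnings(as.integer(f[2]))
    k <- suppressWarnings(as.numeric(f[3]))
    l <- suppressWarnings(as.numeric(f[4]))
    if (any(is.na(c(i, j, k, l))))
      stop("line ", ln, ": non-numeric field")
    if (!f[5] %in% c("P", "L"))
      stop("line ", ln, ": layer must be 'P' or 'L'")
    plastic <- f[5] == "L"
    cr <- if (length(f) == 6) as.numeric(f[6])
          else if (plastic) k / 100 else NA_real_
    if (i == j) stop("line ", ln, ": self-spring (i == j)")
    if (i < 0 || j < 0) stop("line ", ln, ": negative index")
    springs[[length(springs) + 1]] <-
      data.frame(i = i + 1L, j = j + 1L, stiffness = k, natural_length = l,
                 plastic = plastic, creep_rate = cr, line = ln)
  }
  if (!length(springs)) stop("no springs in ", path)
  sp <- do.call(rbind, springs)
  key <- paste(pmin(sp$i, sp$j), pmax(sp$i, sp$j), sp$plastic)
  dup <- which(duplicated(key))
  if (length(dup))
    stop("line ", sp$line[dup[1]], ": duplicate spring for pair (",
         sp$i[dup[1]] - 1L, ", ", sp$j[dup[1]] - 1L, ") in its layer")
  n <- max(sp$i, sp$j,
           if (length(pos_lines)) max(vapply(pos_lines, `[[`, 1L, "i")),
           n_masses %||% 0L)
  if (any(sp$i > n | sp$j > n))
    stop("spring index exceeds n_masses = ", n)
  theta <- 2 * pi * (seq_len(n) - 1) / n
  radius <- max(mean(sp$natural_length), 1e-6)
  pos <- cbind(radius * cos(theta), radius * sin(theta))
  fixed <- rep(FALSE, n)
  for (p in pos_lines) {
    pos[p$i, ] <- c(p$x, p$y)
    fixed[p$i] <- p$fixed
  }
  sp$line <- NULL
  spring_network(pos, sp, fixed = fixed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @param network a [spring_network()] to write.
#' @rdname read_edge_list
#' @return `write_edge_list()`: the path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  sp <- network$springs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# natind edge list: i j stiffness natural_length layer [creep_rate]", con)
  for (m in seq_len(network$n))
    writeLines(sprintf("# pos %d %.17g %.17g%s", m - 1L,
                       network$positions[m, 1], network$positions[m, 2],
                       if (network$fixed[m]) " fixed" else ""), con)
  for (s in seq_len(nrow(sp))) {
    if (sp$plastic[s])
      writeLines(sprintf("%d %d %.17g %.17g L %.17g", sp$i[s] - 1L,
                         sp$j[s] - 1L, sp$stiffness[s],
                         sp$natural_length[s], sp$creep_rate[s]), con)
    else
      writeLines(sprintf("%d %d %.17g %.17g P", sp$i[s] - 1L, sp$j[s] - 1L,
                         sp$stiffness[s], sp$natural_length[s]), con)
  }
  invisible(path)
}

#' Read / write coupling lists for spin-glass problems
#'
#' Whitespace-separated lines `i j J` with 0-based variable indices;
#' `#` comments allowed.
#'
#' @param path file path.
#' @return `read_coupling_list()`: data frame with columns `i, j, J`
#'   (1-based indices).
#' @export
read_coupling_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  rows <- list()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    f <- strsplit(line, "\\s+")[[1]]
    if (length(f) != 3) stop("line ", ln, ": expected 'i j J'")
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v))) stop("line ", ln, ": non-numeric field")
    if (v[1] == v[2]) stop("line ", ln, ": self-coupling")
    rows[[length(rows) + 1]] <-
      data.frame(i = as.integer(v[1]) + 1L, j = as.integer(v[2]) + 1L,
                 J = v[3])
  }
  do.call(rbind, rows)
}

#' @param couplings data frame with columns `i, j, J`.
#' @rdname read_coupling_list
#' @export
write_coupling_list <- function(couplings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# natind coupling list: i j J", con)
  for (r in seq_len(nrow(couplings)))
    writeLines(sprintf("%d %d %.17g", couplings$i[r] - 1L,
                       couplings$j[r] - 1L, couplings$J[r]), con)
  invisible(path)
}

# whitelisted configuration keys, per section
config_schema <- list(
  network = c("scenario", "n", "connect_prob", "natural_length",
              "stiffness", "p_connect", "p_length_range", "p_stiffness",
              "l_connect", "l_length_range", "l_stiffness", "n_vars",
              "edge_prob", "coupling_values", "creep_rate"),
  protocol = c("n_resets", "learning_rate", "n_starts", "late_frac",
               "stress_frac"),
  dynamics = c("damping", "step_size", "equilibrium_tolerance",
               "max_settle_steps", "box_size"),
  output = c("dir", "prefix", "quiet"),
  seed = character(0))

#' Load and save run configurations
#'
#' Configurations are JSON with sections `network`, `protocol`, `dynamics`,
#' `output`, and a top-level `seed`. Every key is optional (documented
#' defaults apply) but unknown keys are rejected by name, so typos fail
#' loudly. The fully resolved configuration is echoed into every run
#' summary.
#'
#' @param path JSON file path.
#' @return `load_config()`: list with the four sections filled with
#'   defaults, a `seed`, and a ready-made [sim_config()] under `$sim`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  unknown_top <- setdiff(names(raw), c(names(config_schema)))
  if (length(unknown_top))
    stop("unknown config section(s): ", paste(unknown_top, collapse = ", "))
  for (sec in setdiff(names(config_schema), "seed")) {
    bad <- setdiff(names(raw[[sec]]), config_schema[[sec]])
    if (length(bad))
      stop("unknown key(s) in '", sec, "': ", paste(bad, collapse = ", "))
  }
  cfg <- list(
    network = utils::modifyList(
      list(scenario = "s1", n = 100, connect_prob = 0.5,
           natural_length = 10, stiffness = 10,
           p_connect = 0.5, p_length_range = c(0, 1), p_stiffness = 1,
           l_connect = 0.99, l_length_range = c(0, 1), l_stiffness = 0.1,
           n_vars = 30, edge_prob = 0.5, coupling_values = c(-1, 1)),
      as.list(raw$network %||% list())),
    protocol = utils::modifyList(
      list(n_resets = 300, learning_rate = 0.02, n_starts = 1000,
           late_frac = 0.25, stress_frac = 0.01),
      as.list(raw$protocol %||% list())),
    dynamics = utils::modifyList(
      list(damping = 1, step_size = 0.01, equilibrium_tolerance = NULL,
           max_settle_steps = 2e5, box_size = NULL),
      as.list(raw$dynamics %||% list())),
    output = utils::modifyList(
      list(dir = ".", prefix = "natind", quiet = FALSE),
      as.list(raw$output %||% list())),
    seed = as.integer(raw$seed %||% 1L))
  cfg$sim <- sim_config(damping = cfg$dynamics$damping,
                        step_size = cfg$dynamics$step_size,
                        equilibrium_tolerance = cfg$dynamics$equilibrium_tolerance,
                        max_settle_steps = cfg$dynamics$max_settle_steps,
                        n_resets = cfg$protocol$n_resets,
                        learning_rate = cfg$protocol$learning_rate,
                        box_size = cfg$dynamics$box_size,
                        seed = cfg$seed)
  cfg
}

#' @param config a configuration list as returned by [load_config()].
#' @rdname load_config
#' @export
save_config <- function(config, path) {
  config$sim <- NULL
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Per-reset trace of a run as CSV
#'
#' Columns: `reset_index`, `settle_steps`, `energy_current`,
#' `energy_original` (NA unless the resettle assay has been run), and
#' `max_plastic_stress` (the audit trail for the timescale-separation
#' contract: plastic stress per settle, hence creep per reset, stays
#' bounded).
#'
#' @param result a `natind_run`.
#' @param path output CSV path.
#' @export
write_trace <- function(result, path) {
  df <- data.frame(
    reset_index = vapply(result$records, `[[`, numeric(1), "reset_index"),
    settle_steps = vapply(result$records, `[[`, numeric(1), "settle_steps"),
    energy_current = vapply(result$records, `[[`, numeric(1),
                            "energy_current"),
    energy_original = vapply(result$records, `[[`, numeric(1),
                             "energy_original"),
    max_plastic_stress = vapply(result$records, function(r)
      r$max_plastic_stress %||% NA_real_, numeric(1)))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' JSON summary of a run
#'
#' Schema-versioned (`natind/1`) document with the seed, a full config
#' echo, the per-reset energy summary, and whatever assay scores are
#' supplied (e.g. from [scenario1_scores()] or [scenario2_scores()]).
#'
#' @param result a `natind_run`.
#' @param assays optional named list of assay outputs; numeric scalars are
#'   copied into the summary.
#' @param path optional path to also write the JSON to.
#' @return the summary as a list (invisibly if `path` given).
#' @export
run_summary <- function(result, assays = list(), path = NULL) {
  ec <- vapply(result$records, `[[`, numeric(1), "energy_current")
  doc <- list(
    schema = "natind/1",
    scenario = result$scenario,
    seed = result$config$seed,
    config = unclass(result$config),
    n_resets = length(result$records),
    energy_current = list(first = ec[1], last = ec[length(ec)],
                          min = min(ec)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(result$energy_p)) {
    doc$energy_p <- result$energy_p
    doc$energy_l <- result$energy_l
  }
  keep <- Filter(function(x) is.numeric(x) && length(x) == 1, assays)
  doc$assays <- keep
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
    return(invisible(doc))
  }
  doc
}
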