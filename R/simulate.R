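#' Simulation configuration
#'
#' Collects the embodied-simulation parameters. The neural timescale is
#' kept much faster than movement: `neural_steps_per_move` Metropolis
#' proposals (default `10 * n_spins`) run between consecutive movement
#' updates, with an equal burn-in before the first move.
#'
#' @param n_spins network size `N`.
#' @param nu neural tuning in `(0, 1]`.
#' @param T neural noise temperature (> 0).
#' @param sigma_e directional-noise circular SD (radians, >= 0).
#' @param v0 speed proportionality constant (length per step, > 0).
#' @param dt movement time step.
#' @param neural_steps_per_move Metropolis proposals per movement step.
#' @param burn_in proposals before the first movement step (default
#'   `neural_steps_per_move`).
#' @param stop_radius capture distance to a target.
#' @param max_steps maximum number of movement steps.
#' @param start agent start position (length-2).
#' @param allocation optional per-target spin counts (see [spin_network()]).
#' @param seed RNG seed or `NULL`.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_spins = 60L, nu = 0.7, T = 0.5, sigma_e = 0.3,
                       v0 = 0.1, dt = 1, neural_steps_per_move = 10L * n_spins,
                       burn_in = neural_steps_per_move, stop_radius = 0.01,
                       max_steps = 2000L, start = c(0, 0),
                       allocation = NULL, seed = NULL) {
  stopifnot(n_spins >= 1, nu > 0, nu <= 1, T > 0, sigma_e >= 0,
            v0 > 0, dt > 0, neural_steps_per_move >= 1,
            stop_radius >= 0, max_steps >= 1, length(start) == 2)
  structure(list(n_spins = as.integer(n_spins), nu = nu, T = T,
                 sigma_e = sigma_e, v0 = v0, dt = dt,
                 neural_steps_per_move = as.integer(neural_steps_per_move),
                 burn_in = as.integer(burn_in),
                 stop_radius = stop_radius, max_steps = as.integer(max_steps),
                 start = as.numeric(start), allocation = allocation,
                 seed = seed),
            class = "sim_config")
}

#' Simulate one embodied decision trajectory
#'
#' Closed loop: refresh each spin's goal vector from the agent's current
#' position (with directional noise), run `neural_steps_per_move`
#' Metropolis proposals at temperature `T`, move the agent by the consensus
#' velocity, advance any moving targets, and repeat until capture
#' (distance to a target at most `stop_radius`; ties broken by smallest
#' target index) or `max_steps`.
#'
#' @param targets a [target_set()].
#' @param config a [sim_config()]; its `n_spins` must be divisible by
#'   `targets$k` unless `allocation` is given.
#' @param record_targets keep per-step target positions (needed for
#'   moving-frame analyses).
#' @param trial_id identifier stored in the output.
#' @return a `spin_trajectory`: data frame with columns `trial_id`, `time`,
#'   `x`, `y`, and attributes `outcome` (captured target index or `NA`),
#'   `group_activity` (steps x k matrix of per-target active fractions),
#'   `target_pos`, `target_dir`, `config`, `targets`, `seed`.
#' @examples
#' ts <- make_static_geometry("two-choice", distance = 10,
#'                            angular_span = 60 * pi / 180)
#' tr <- simulate_trajectory(ts, sim_config(seed = 1, T = 0.3,
#'                                          stop_radius = 0.25))
#' attr(tr, "outcome")
#' @export
simulate_trajectory <- function(targets, config = sim_config(),
                                record_targets = !is.null(targets$motion),
                                trial_id = 1L) {
  stopifnot(inherits(targets, "target_set"), inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  k <- targets$k
  allocation <- config$allocation
  if (is.null(allocation)) {
    if (config$n_spins %% k != 0)
      stop("n_spins must be divisible by k (or pass an explicit allocation)")
    allocation <- rep(config$n_spins %/% k, k)
  }
  assignment <- rep(seq_len(k), allocation) - 1L
  moving <- !is.null(targets$motion)
  mot <- targets$motion %||% list(axis = c(1, 0), speed = 0, bounds = c(0, 0))
  out <- cpp_simulate_trajectory(
    targets$positions, as.integer(assignment), config$nu, config$T,
    config$sigma_e, config$v0, config$dt, config$neural_steps_per_move,
    config$burn_in, config$max_steps, config$stop_radius, config$start,
    moving, mot$axis, mot$speed, mot$bounds, record_targets)
  n <- out$n_steps
  idx <- seq_len(n + 1L)
  df <- data.frame(trial_id = trial_id, time = (idx - 1L) * config$dt,
                   x = out$pos[idx, 1], y = out$pos[idx, 2])
  structure(df,
            outcome = if (out$outcome > 0) out$outcome else NA_integer_,
            group_activity = out$group_activity[idx, , drop = FALSE],
            target_pos = if (record_targets)
              out$target_pos[idx, , drop = FALSE] else NULL,
            target_dir = if (record_targets) out$target_dir[idx] else NULL,
            config = config, targets = targets, seed = config$seed,
            class = c("spin_trajectory", "data.frame"))
}

#' Simulate replicate trajectories
#'
#' Replicate `r` runs with seed `base_seed + r`, so any single replicate is
#' reproducible in isolation.
#'
#' @param n_reps number of replicates.
#' @param targets a [target_set()].
#' @param config a [sim_config()]; its `seed` field is ignored.
#' @param base_seed integer base seed.
#' @param record_targets see [simulate_trajectory()].
#' @return a `trajectory_ensemble`: list of `spin_trajectory` objects with
#'   attribute `outcomes` (integer vector, `NA` = no capture).
#' @export
simulate_replicates <- function(n_reps, targets, config = sim_config(),
                                base_seed = 1L,
                                record_targets = !is.null(targets$motion)) {
  stopifnot(n_reps >= 1)
  trs <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- base_seed + r
    trs[[r]] <- simulate_trajectory(targets, cfg, record_targets,
                                    trial_id = r)
  }
  structure(trs,
            outcomes = vapply(trs, function(t) {
              o <- attr(t, "outcome"); if (is.na(o)) NA_integer_ else o
            }, integer(1)),
            targets = targets, config = config, base_seed = base_seed,
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  oc <- attr(x, "outcomes")
  cat(sprintf("<trajectory_ensemble> %d trajectories; outcomes: %s\n",
              length(x),
              paste(sprintf("%s=%d", names(table(oc, useNA = "ifany")),
                            as.integer(table(oc, useNA = "ifany"))),
                    collapse = " ")))
  invisible(x)
}

#' Bind an ensemble into one long data frame
#'
#' @param ensemble a `trajectory_ensemble` (or list of trajectory data
#'   frames with columns `trial_id`, `time`, `x`, `y`).
#' @return data frame with columns `trial_id`, `time`, `x`, `y`.
#' @export
bind_trajectories <- function(ensemble) {
  do.call(rbind, lapply(ensemble, function(t)
    as.data.frame(t)[, c("trial_id", "time", "x", "y")]))
}

#' Write / read trajectory ensembles as delimited text
#'
#' The on-disk schema is a CSV with columns `trial_id`, `time`, `x`, `y`
#' plus an optional JSON sidecar (`<file>.json`) holding outcomes, seeds
#' and the resolved configuration for provenance.
#'
#' @param ensemble a `trajectory_ensemble`.
#' @param file CSV path.
#' @param sidecar write the JSON sidecar.
#' @return `file`, invisibly.
#' @export
write_trajectories <- function(ensemble, file, sidecar = TRUE) {
  write.csv(bind_trajectories(ensemble), file, row.names = FALSE)
  if (sidecar) {
    cfg <- attr(ensemble, "config")
    meta <- list(outcomes = as.integer(attr(ensemble, "outcomes")),
                 base_seed = attr(ensemble, "base_seed"),
                 config = cfg[setdiff(names(cfg), "allocation")],
                 targets = list(
                   positions = attr(ensemble, "targets")$positions,
                   k = attr(ensemble, "targets")$k))
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)
  }
  invisible(file)
}

#' @rdname write_trajectories
#' @param file CSV path with columns `trial_id`, `time`, `x`, `y`.
#' @return `read_trajectories`: a list of per-trial data frames (ordered by
#'   time), usable by the analysis functions.
#' @export
read_trajectories <- function(file) {
  df <- read.csv(file)
  need <- c("trial_id", "time", "x", "y")
  if (!all(need %in% names(df)))
    stop("trajectory file must have columns trial_id, time, x, y")
  out <- split(df[, need], df$trial_id)
  lapply(out, function(d) d[order(d$time), , drop = FALSE])
}
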