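#' Collective-model configuration
#'
#' Parameters of the zonal collective-motion model: repulsion has absolute
#' priority inside `zor`; otherwise agents are attracted to and align with
#' neighbours inside `zoa`. Informed agents blend the social direction with
#' a unit goal vector weighted by omega; with `feedback = TRUE` omega is
#' adapted by `omega' = clip(omega + gain * dt * (cos(beta) - c0), 0,
#' omega_max)`, where beta is the angle between the agent's movement
#' direction and its goal direction, so agents dragged away from their goal
#' progressively give it up.
#'
#' @param n_informed_per_target integer vector: informed agents per target.
#' @param n_uninformed number of unbiased agents.
#' @param zor,zoa repulsion and interaction zone radii (`zor < zoa`).
#' @param speed common speed.
#' @param theta_max maximum turning rate (rad per time unit).
#' @param sigma_h per-step heading noise SD (radians).
#' @param dt time step.
#' @param omega0 initial goal weight of informed agents.
#' @param omega_max upper bound on omega.
#' @param gain feedback gain (> 0).
#' @param c0 mismatch threshold: omega grows when `cos(beta) > c0`.
#' @param feedback enable the omega feedback.
#' @param stop_radius centroid capture distance.
#' @param split_threshold single-linkage distance above which the group
#'   counts as split.
#' @param split_check_every steps between split checks.
#' @param max_steps step budget.
#' @param start_spread agents start uniformly in a disk of this radius.
#' @param start_heading_sd SD (radians) of initial headings around the
#'   bearing to the targets' center of mass; `Inf` for uniformly random
#'   initial headings.
#' @param seed RNG seed or `NULL`.
#' @return a list of class `collective_config`.
#' @export
collective_config <- function(n_informed_per_target = c(5L, 5L),
                              n_uninformed = 0L, zor = 1, zoa = 8,
                              speed = 1, theta_max = 2, sigma_h = 0.02,
                              dt = 0.1, omega0 = 0.5, omega_max = 0.8,
                              gain = 1, c0 = 0.5, feedback = TRUE,
                              stop_radius = 3, split_threshold = 10,
                              split_check_every = 10L, max_steps = 3000L,
                              start_spread = 3, start_heading_sd = 0.5,
                              seed = NULL) {
  stopifnot(all(n_informed_per_target >= 0), n_uninformed >= 0,
            sum(n_informed_per_target) + n_uninformed >= 2,
            zor < zoa, zor > 0, speed > 0, theta_max > 0, dt > 0,
            omega0 >= 0, omega0 <= omega_max, gain > 0,
            split_threshold > 0)
  structure(as.list(environment()), class = "collective_config")
}

#' Simulate one collective decision
#'
#' Synchronous zonal-model update with turning-rate cap `theta_max * dt`
#' and wrapped-Gaussian heading noise. The run ends when the group centroid
#' comes within `stop_radius` of a target, when the group splits into more
#' than one single-linkage cluster at `split_threshold`, or at `max_steps`.
#'
#' @param targets a [target_set()] (static).
#' @param config a [collective_config()] whose informed counts match
#'   `targets$k`.
#' @param record_agents keep per-agent positions per step.
#' @return list of class `collective_run`: `centroid` (data frame `time`,
#'   `x`, `y`), `outcome` (`"target_<j>"`, `"split"` or `"timeout"`),
#'   `outcome_target` (integer or `NA`), final `omega` and `pos`, optional
#'   `agent_pos`.
#' @export
simulate_group <- function(targets, config = collective_config(),
                           record_agents = FALSE) {
  stopifnot(inherits(targets, "target_set"),
            inherits(config, "collective_config"),
            length(config$n_informed_per_target) == targets$k)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- sum(config$n_informed_per_target) + config$n_uninformed
  goal <- c(rep(seq_len(targets$k), config$n_informed_per_target),
            rep(0L, config$n_uninformed)) - 1L
  r <- config$start_spread * sqrt(runif(n))
  a <- runif(n, -pi, pi)
  pos0 <- cbind(r * cos(a), r * sin(a))
  # released oriented toward the scene unless start_heading_sd = Inf
  if (is.finite(config$start_heading_sd)) {
    com <- colMeans(targets$positions)
    b <- atan2(com[2], com[1])
    heading0 <- wrap_angle(b + rnorm(n, 0, config$start_heading_sd))
  } else {
    heading0 <- runif(n, -pi, pi)
  }
  omega0 <- ifelse(goal >= 0, config$omega0, 0)
  out <- cpp_simulate_group(pos0, heading0, as.integer(goal),
                            targets$positions, config$speed, config$dt,
                            config$zor, config$zoa, config$theta_max,
                            config$sigma_h, omega0, config$omega_max,
                            config$gain, config$c0, config$feedback,
                            config$stop_radius, config$split_threshold,
                            as.integer(config$split_check_every),
                            as.integer(config$max_steps), record_agents)
  idx <- seq_len(out$n_steps + 1L)
  outcome_target <- if (out$outcome > 0) out$outcome else NA_integer_
  outcome <- if (out$outcome > 0) paste0("target_", out$outcome)
             else if (out$outcome < 0) "split" else "timeout"
  structure(list(centroid = data.frame(time = (idx - 1L) * config$dt,
                                       x = out$centroid[idx, 1],
                                       y = out$centroid[idx, 2]),
                 outcome = outcome, outcome_target = outcome_target,
                 omega = out$omega, pos = out$pos,
                 agent_pos = if (record_agents)
                   out$agent_pos[idx, , drop = FALSE] else NULL,
                 config = config, targets = targets),
            class = "collective_run")
}

#' Replicate collective simulations
#'
#' Replicate `r` uses seed `base_seed + r`.
#'
#' @param n_reps number of replicates.
#' @param targets a [target_set()].
#' @param config a [collective_config()] (its `seed` is ignored).
#' @param base_seed integer base seed.
#' @return list of class `collective_ensemble` with attribute `outcomes`
#'   (character vector).
#' @export
simulate_group_replicates <- function(n_reps, targets,
                                      config = collective_config(),
                                      base_seed = 1L) {
  runs <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- base_seed + r
    runs[[r]] <- simulate_group(targets, cfg)
  }
  structure(runs,
            outcomes = vapply(runs, `[[`, character(1), "outcome"),
            targets = targets, config = config, base_seed = base_seed,
            class = "collective_ensemble")
}

#' Centroid trajectories of the non-split replicates
#'
#' @param ensemble a `collective_ensemble`.
#' @return list of centroid data frames (`trial_id`, `time`, `x`, `y`)
#'   restricted to replicates that neither split nor timed out.
#' @export
centroid_trajectories <- function(ensemble) {
  keep <- which(startsWith(attr(ensemble, "outcomes"), "target_"))
  lapply(seq_along(keep), function(i) {
    d <- ensemble[[keep[i]]]$centroid
    cbind(trial_id = i, d)
  })
}

#' Group-split detector
#'
#' Single-linkage clustering at `threshold`: the group is split when the
#' agent positions form more than one connected component under the
#' "within `threshold` of some other member" relation. A pair exactly at
#' the threshold is connected (closed rule).
#'
#' @param positions n x 2 matrix of agent positions (n >= 2).
#' @param threshold linkage distance.
#' @return logical: `TRUE` when the group is split.
#' @export
split_detector <- function(positions, threshold) {
  positions <- as.matrix(positions)
  stopifnot(nrow(positions) >= 2, ncol(positions) == 2, threshold > 0)
  cpp_count_components(positions, threshold) > 1L
}
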