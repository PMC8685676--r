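#' Zonal social direction
#'
#' Reference implementation of the zonal interaction rule used by the
#' collective simulator (the C++ loop applies the identical rule; a unit
#' test holds the two in agreement). Repulsion has absolute priority:
#' if any neighbour is inside `zor` the desired direction is the
#' normalized sum of unit vectors away from those neighbours. Otherwise
#' the desired direction combines attraction to and alignment with
#' neighbours inside `zoa` (alignment includes the agent's own heading).
#' With no neighbour in range the agent keeps its current heading.
#'
#' @param position length-2 agent position.
#' @param heading length-2 unit vector (current heading).
#' @param neighbor_pos matrix (possibly 0-row) of neighbour positions.
#' @param neighbor_headings matrix of neighbour heading unit vectors.
#' @param zor,zoa zone radii (`zor < zoa`).
#' @return unit 2-vector.
#' @export
zonal_social_direction <- function(position, heading, neighbor_pos,
                                   neighbor_headings, zor, zoa) {
  stopifnot(zor > 0, zor < zoa)
  neighbor_pos <- matrix(neighbor_pos, ncol = 2)
  neighbor_headings <- matrix(neighbor_headings, ncol = 2)
  if (nrow(neighbor_pos) == 0L) return(heading / sqrt(sum(heading^2)))
  d <- sweep(neighbor_pos, 2, position)
  r <- sqrt(rowSums(d^2))
  rep_idx <- which(r <= zor & r > 0)
  if (length(rep_idx)) {
    v <- -colSums(d[rep_idx, , drop = FALSE] / r[rep_idx])
    if (sum(v^2) == 0) return(heading / sqrt(sum(heading^2)))
    return(v / sqrt(sum(v^2)))
  }
  soc_idx <- which(r <= zoa & r > 0)
  if (!length(soc_idx)) return(heading / sqrt(sum(heading^2)))
  v <- colSums(d[soc_idx, , drop = FALSE] / r[soc_idx]) +
    colSums(neighbor_headings[soc_idx, , drop = FALSE]) + heading
  if (sum(v^2) < 1e-24) return(heading / sqrt(sum(heading^2)))
  v / sqrt(sum(v^2))
}

#' Blend a social direction with a goal direction
#'
#' `d = (s + omega * g) / |s + omega * g|`: at `omega = 0` the agent is
#' purely social; as `omega` grows the goal dominates. Continuous in
#' `omega`.
#'
#' @param social_dir,goal_dir unit 2-vectors.
#' @param omega goal weight (>= 0).
#' @return unit 2-vector.
#' @export
informed_direction <- function(social_dir, goal_dir, omega) {
  stopifnot(omega >= 0)
  v <- social_dir + omega * goal_dir
  n <- sqrt(sum(v^2))
  if (n < 1e-12) return(social_dir)
  v / n
}

#' Mismatch feedback on the goal weight
#'
#' `omega' = clip(omega + gain * dt * (cos_beta - c0), 0, omega_max)`:
#' moving with one's goal (`cos_beta > c0`) reinforces the preference,
#' moving against it erodes it.
#'
#' @param omega current weight.
#' @param cos_mismatch cosine of the angle between movement direction and
#'   goal direction.
#' @param gain feedback gain (> 0).
#' @param dt time step.
#' @param c0 neutral cosine.
#' @param omega_max upper bound.
#' @return updated omega in `[0, omega_max]`.
#' @export
omega_feedback <- function(omega, cos_mismatch, gain, dt, c0 = 0.5,
                           omega_max = 0.8) {
  stopifnot(gain > 0, omega_max >= 0)
  min(max(omega + gain * dt * (cos_mismatch - c0), 0), omega_max)
}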