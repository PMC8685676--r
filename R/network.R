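#' Direction-dependent interaction strength
#'
#' The coupling between two spins whose preferred directions differ by
#' `theta` is \eqn{J(\theta) = \cos(\pi (\theta/\pi)^\nu)}. For `nu = 1`
#' the kernel is plain cosine (a Euclidean representation of direction);
#' `nu < 1` sharpens excitation around small angular differences while
#' keeping \eqn{J(0) = 1} and \eqn{J(\pi) = -1}.
#'
#' @param theta angular difference(s) in radians, in `[0, pi]`.
#' @param nu neural tuning parameter in `(0, 1]`.
#' @return numeric vector of couplings in `[-1, 1]`.
#' @examples
#' interaction_strength(pi / 4, nu = 0.5)  # exactly 0
#' @export
interaction_strength <- function(theta, nu) {
  if (!is.numeric(nu) || length(nu) != 1L || nu <= 0 || nu > 1)
    stop("`nu` must be a scalar in (0, 1]")
  theta <- as.numeric(theta)
  tol <- 1e-9
  if (any(theta < -tol | theta > pi + tol))
    stop("`theta` must lie in [0, pi] after angle normalization")
  as.numeric(cpp_interaction(pmin(pmax(theta, 0), pi), nu))
}

#' Construct a spin network
#'
#' `N` binary spins, each assigned to one target and carrying a unit
#' preferred direction (the egocentric goal vector of its target). By
#' default spins are split equally over targets (`N` must then be divisible
#' by `k`); an explicit per-target allocation models unequal preference.
#' Initial states are i.i.d. Bernoulli(1/2) unless supplied.
#'
#' @param n_spins total number of spins `N`.
#' @param k number of targets.
#' @param nu neural tuning in `(0, 1]`.
#' @param allocation optional integer vector of per-target spin counts
#'   (length `k`, summing to `n_spins`); default equal split.
#' @param preferred_angles optional numeric vector (length `n_spins`) of
#'   initial preferred directions (radians); default: all zero until the
#'   first [refresh_goal_vectors()].
#' @param states optional 0/1 vector of initial spin states.
#' @return an object of class `spin_network` with fields `n_spins`, `k`,
#'   `nu`, `assignment` (spin to target, 1-based), `angles`, `states`.
#' @export
spin_network <- function(n_spins, k, nu = 0.7, allocation = NULL,
                         preferred_angles = NULL, states = NULL) {
  stopifnot(n_spins >= k, k >= 1, nu > 0, nu <= 1)
  if (is.null(allocation)) {
    if (n_spins %% k != 0)
      stop("`n_spins` must be divisible by `k` for the equal allocation; ",
           "pass `allocation` explicitly for unequal preference")
    allocation <- rep(n_spins %/% k, k)
  }
  allocation <- as.integer(allocation)
  if (length(allocation) != k || sum(allocation) != n_spins)
    stop("`allocation` must have length k and sum to n_spins")
  if (any(allocation < 1L))
    stop("every target needs at least one assigned spin")
  assignment <- rep(seq_len(k), allocation)
  if (is.null(preferred_angles)) preferred_angles <- numeric(n_spins)
  stopifnot(length(preferred_angles) == n_spins)
  if (is.null(states)) states <- rbinom(n_spins, 1L, 0.5)
  states <- as.integer(states)
  stopifnot(length(states) == n_spins, all(states %in% c(0L, 1L)))
  structure(list(n_spins = as.integer(n_spins), k = as.integer(k),
                 nu = nu, assignment = assignment,
                 angles = as.numeric(preferred_angles), states = states),
            class = "spin_network")
}

#' @export
print.spin_network <- function(x, ...) {
  cat(sprintf("<spin_network> N = %d spins, k = %d targets, nu = %.3g, %d active\n",
              x$n_spins, x$k, x$nu, sum(x$states)))
  invisible(x)
}

#' Unit preferred-direction vectors of a network
#'
#' @param network a [spin_network()].
#' @return `n_spins` x 2 matrix of unit vectors.
#' @export
preferred_dirs <- function(network) {
  cbind(cos(network$angles), sin(network$angles))
}

#' Pairwise coupling matrix of a network
#'
#' Couplings `J[i, j] = interaction_strength(theta_ij, nu)` recomputed from
#' the current preferred directions (never cached across goal-vector
#' refreshes); diagonal zero.
#'
#' @param network a [spin_network()].
#' @return symmetric `n_spins` x `n_spins` matrix.
#' @export
coupling_matrix <- function(network) {
  cpp_coupling_matrix(network$angles, network$nu)
}

#' Network energy
#'
#' \eqn{H = -(k/N) \sum_{i \ne j} J_{ij} \sigma_i \sigma_j}, the sum
#' running over ordered pairs.
#'
#' @param network a [spin_network()].
#' @param k number of options; defaults to the network's own `k`.
#' @return scalar energy.
#' @export
hamiltonian <- function(network, k = network$k) {
  stopifnot(k >= 1)
  J <- coupling_matrix(network)
  s <- network$states
  -(k / network$n_spins) * drop(s %*% J %*% s)
}

#' Consensus velocity of the active spins
#'
#' \eqn{V = (v_0/N) \sum_i \hat p_i \sigma_i}: the normalized resultant of
#' active goal vectors, so speed never exceeds `v0`.
#'
#' @param network a [spin_network()].
#' @param v0 speed proportionality constant (> 0).
#' @return length-2 velocity vector.
#' @export
consensus_velocity <- function(network, v0 = 1) {
  stopifnot(v0 > 0)
  p <- preferred_dirs(network)
  (v0 / network$n_spins) * colSums(p * network$states)
}

#' Refresh egocentric goal vectors
#'
#' Points every spin's preferred direction from `agent_position` to its
#' assigned target, each rotated by an independent draw from a wrapped
#' Gaussian with SD `sigma_e`. Errors out if the agent coincides with a
#' target (that situation must be resolved by capture, not silently).
#'
#' @param network a [spin_network()].
#' @param agent_position length-2 numeric.
#' @param targets a [target_set()] with `k` equal to the network's.
#' @param sigma_e directional-noise circular SD (radians, >= 0).
#' @param offset travel-axis offset for moving targets.
#' @return the network with updated `angles`.
#' @export
refresh_goal_vectors <- function(network, agent_position, targets,
                                 sigma_e = 0, offset = 0) {
  stopifnot(inherits(network, "spin_network"),
            inherits(targets, "target_set"),
            targets$k == network$k, sigma_e >= 0)
  pos <- target_positions(targets, offset)
  d <- pos[network$assignment, , drop = FALSE] -
    matrix(agent_position, network$n_spins, 2, byrow = TRUE)
  r <- sqrt(rowSums(d^2))
  if (any(r == 0))
    stop("agent is coincident with a target; bearing undefined ",
         "(should have been captured)")
  b <- atan2(d[, 2], d[, 1])
  if (sigma_e > 0) b <- b + rnorm(network$n_spins, 0, sigma_e)
  network$angles <- wrap_angle(b)
  network
}

#' Run Metropolis proposals on a spin network
#'
#' Each proposal picks one spin uniformly at random and flips it with
#' probability `min(1, exp(-dH/T))`. At frozen geometry the chain satisfies
#' detailed balance with stationary weights proportional to `exp(-H/T)`.
#'
#' @param network a [spin_network()].
#' @param T neural noise temperature (> 0).
#' @param n_steps number of proposals.
#' @param thin record the order parameter / state every `thin` proposals
#'   (0 = record nothing).
#' @param record_states also record full spin states at each thinning point.
#' @return list with the updated `network`, numeric vectors `m` (two-group
#'   order parameter) and `activity` (active fraction), and (optionally)
#'   integer matrix `state_trace`.
#' @export
metropolis <- function(network, T, n_steps, thin = 0L,
                       record_states = FALSE) {
  stopifnot(T > 0, n_steps >= 0)
  J <- coupling_matrix(network)
  out <- cpp_metropolis_chain(J, network$states, network$k, T,
                              as.integer(n_steps), as.integer(thin),
                              network$assignment - 1L, record_states)
  network$states <- out$states
  list(network = network, m = out$m, activity = out$activity,
       state_trace = if (record_states) out$state_trace else NULL)
}
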