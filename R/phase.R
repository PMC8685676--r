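#' Two-group order parameter
#'
#' For a two-target network, `m = (n1 - n2) / (n1 + n2)` where `n_g` is the
#' number of active spins assigned to target `g`; `m = 0` when no spin is
#' active. `m = 0` is the compromise state, `m = +/-1` a pure decision.
#'
#' @param network a [spin_network()] with `k = 2`, or an integer 0/1 state
#'   vector accompanied by `group`.
#' @param group integer vector of group labels (1 or 2) when `network` is a
#'   plain state vector.
#' @return scalar in `[-1, 1]`.
#' @export
order_parameter <- function(network, group = NULL) {
  if (inherits(network, "spin_network")) {
    if (network$k != 2L) stop("order_parameter is defined for k = 2")
    states <- network$states
    group <- network$assignment
  } else {
    states <- as.integer(network)
    if (is.null(group)) stop("`group` required for a plain state vector")
  }
  n1 <- sum(states[group == 1L])
  n2 <- sum(states[group == 2L])
  if (n1 + n2 == 0L) return(0)
  (n1 - n2) / (n1 + n2)
}

#' Fluctuation susceptibility
#'
#' \eqn{\chi = N (\langle m^2 \rangle - \langle m \rangle^2) / T}, the
#' fluctuation-dissipation estimator with population (divide-by-n)
#' variance.
#'
#' @param m_samples numeric vector of order-parameter samples (>= 2).
#' @param T temperature (> 0).
#' @param N system size used in the normalization.
#' @return nonnegative scalar.
#' @export
susceptibility <- function(m_samples, T, N) {
  stopifnot(length(m_samples) >= 2, T > 0, N >= 1)
  v <- mean(m_samples^2) - mean(m_samples)^2
  max(N * v / T, 0)
}

# Frozen two-target network: groups at bearings +/- theta/2, agent fixed,
# goal vectors noiseless.
frozen_network <- function(theta, nu, N, states = NULL) {
  stopifnot(theta >= 0, theta <= pi, N %% 2 == 0)
  spin_network(N, 2L, nu = nu,
               preferred_angles = rep(c(-theta / 2, theta / 2),
                                      each = N / 2),
               states = states)
}

# Expected |m| under independent Bernoulli(1/2) spins (the high-T null),
# by direct Monte Carlo; cheap and only used to label regimes.
null_abs_m <- function(N, n_draws = 2000) {
  n1 <- rbinom(n_draws, N / 2, 0.5)
  n2 <- rbinom(n_draws, N / 2, 0.5)
  tot <- n1 + n2
  mean(ifelse(tot == 0, 0, abs(n1 - n2) / pmax(tot, 1)))
}

# Regime label from chain summaries. decision: strong symmetry breaking;
# compromise: |m| pinned well below even the independent-spin null
# (both groups coherently active); disordered: |m| at the null level.
label_regime <- function(mean_abs_m, null_m,
                         decision_threshold = 0.5, null_factor = 0.75) {
  if (mean_abs_m >= decision_threshold) "decision"
  else if (mean_abs_m <= null_factor * null_m) "compromise"
  else "disordered"
}

#' Stationary scan over geometry and noise
#'
#' Equilibrium Monte Carlo characterization of the frozen two-target
#' network on a grid of inter-target angle `theta` and temperature `T`.
#' Per grid point, `reps` independent chains are run from random states;
#' the first half of each chain is discarded and the rest thinned every
#' `N` proposals. Reports the mean absolute order parameter, its variance,
#' susceptibility, activity, a split-chain equilibration diagnostic, and a
#' regime label in `{compromise, decision, disordered}`.
#'
#' @param theta_grid inter-target angles (radians, in `[0, pi]`).
#' @param T_grid temperatures (> 0).
#' @param nu neural tuning.
#' @param N network size (even).
#' @param reps chains per grid point.
#' @param sweeps chain length in units of `N` proposals.
#' @param seed RNG seed or `NULL`.
#' @param decision_threshold,null_factor regime-label thresholds (see
#'   Details in the package vignette).
#' @return a `phase_diagram`: data frame with one row per grid point and
#'   columns `theta`, `T`, `mean_abs_m`, `var_m`, `chi`, `activity`,
#'   `regime`, `equil_gap`.
#' @export
stationary_scan <- function(theta_grid, T_grid, nu = 0.7, N = 60L,
                            reps = 4L, sweeps = 600L, seed = NULL,
                            decision_threshold = 0.5, null_factor = 0.75) {
  stopifnot(length(theta_grid) >= 1, length(T_grid) >= 1, reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  null_m <- null_abs_m(N)
  grid <- expand.grid(theta = theta_grid, T = T_grid)
  res <- lapply(seq_len(nrow(grid)), function(g) {
    theta <- grid$theta[g]; Tg <- grid$T[g]
    ms <- list(); act <- 0; gap <- 0
    for (r in seq_len(reps)) {
      net <- frozen_network(theta, nu, N)
      ch <- metropolis(net, Tg, n_steps = sweeps * N, thin = N)
      keep <- ch$m[-seq_len(length(ch$m) %/% 2)]
      h1 <- mean(abs(keep[seq_len(length(keep) %/% 2)]))
      h2 <- mean(abs(keep[-seq_len(length(keep) %/% 2)]))
      gap <- max(gap, abs(h1 - h2))
      ms[[r]] <- keep
      act <- act + mean(ch$activity[-seq_len(length(ch$activity) %/% 2)])
    }
    m_all <- unlist(ms)
    data.frame(theta = theta, T = Tg,
               mean_abs_m = mean(abs(m_all)),
               var_m = mean(m_all^2) - mean(m_all)^2,
               chi = susceptibility(m_all, Tg, N),
               activity = act / reps,
               regime = label_regime(mean(abs(m_all)), null_m,
                                     decision_threshold, null_factor),
               equil_gap = gap)
  })
  out <- do.call(rbind, res)
  attr(out, "nu") <- nu
  attr(out, "N") <- N
  attr(out, "null_abs_m") <- null_m
  class(out) <- c("phase_diagram", "data.frame")
  out
}

#' Hysteresis detection along a fixed-temperature angle sweep
#'
#' Sweeps the inter-target angle up and then down, carrying the spin state
#' across consecutive grid points within each sweep. Points where the two
#' sweeps assign different regime labels mark the bistable interval, where
#' compromise and decision solutions coexist.
#'
#' @param theta_grid increasing angle grid (radians); must be nonempty.
#' @param T temperature.
#' @param nu,N as in [stationary_scan()].
#' @param sweeps chain length per grid point in units of `N` proposals.
#' @param seed RNG seed or `NULL`.
#' @param decision_threshold,null_factor regime-label thresholds.
#' @return list with `interval` (range of disagreeing thetas, or `NULL`
#'   when the sweeps agree everywhere), and the per-point labels `up`,
#'   `down`.
#' @export
detect_bistability <- function(theta_grid, T, nu = 0.7, N = 60L,
                               sweeps = 400L, seed = NULL,
                               decision_threshold = 0.5,
                               null_factor = 0.75) {
  if (length(theta_grid) == 0) stop("empty theta grid")
  if (is.unsorted(theta_grid)) stop("`theta_grid` must be increasing")
  if (!is.null(seed)) set.seed(seed)
  null_m <- null_abs_m(N)
  sweep_labels <- function(grid, init_states) {
    states <- init_states
    labs <- character(length(grid))
    for (i in seq_along(grid)) {
      net <- frozen_network(grid[i], nu, N, states = states)
      ch <- metropolis(net, T, n_steps = sweeps * N, thin = N)
      states <- ch$network$states
      keep <- abs(ch$m[-seq_len(length(ch$m) %/% 2)])
      labs[i] <- label_regime(mean(keep), null_m,
                              decision_threshold, null_factor)
    }
    labs
  }
  # up sweep starts from the all-on compromise state, down sweep from a
  # one-sided decision state: the protocol probes both attractors
  n_half <- N %/% 2
  up <- sweep_labels(theta_grid, rep(1L, N))
  down <- rev(sweep_labels(rev(theta_grid),
                           rep(c(1L, 0L), c(n_half, N - n_half))))
  # bistability proper: the sweep started in the compromise basin is still
  # there while the sweep started in the decision basin is still decided
  differ <- up == "compromise" & down == "decision"
  list(interval = if (any(differ)) range(theta_grid[differ]) else NULL,
       up = up, down = down, theta = theta_grid)
}

#' Estimate the critical temperature
#'
#' Runs [detect_bistability()] on each temperature of `T_grid` (increasing)
#' and reports `T_c` as the midpoint between the last temperature with a
#' nonempty bistable interval and the first one above it where the interval
#' is empty.
#'
#' @param T_grid increasing temperatures.
#' @param theta_grid angle grid for the sweeps.
#' @param nu,N,sweeps,seed as in [detect_bistability()].
#' @return list with `T_c` (`NA` if bistability never appears or never
#'   disappears on the grid) and the per-temperature `intervals`.
#' @export
estimate_Tc <- function(T_grid, theta_grid, nu = 0.7, N = 60L,
                        sweeps = 400L, seed = NULL) {
  stopifnot(!is.unsorted(T_grid))
  ints <- vector("list", length(T_grid))
  for (i in seq_along(T_grid)) {
    s <- if (is.null(seed)) NULL else seed + i
    ints[i] <- list(detect_bistability(theta_grid, T_grid[i], nu, N,
                                       sweeps = sweeps, seed = s)$interval)
  }
  nonempty <- !vapply(ints, is.null, logical(1))
  T_c <- NA_real_
  if (any(nonempty) && !nonempty[length(nonempty)]) {
    last_on <- max(which(nonempty))
    first_off <- min(which(!nonempty & seq_along(nonempty) > last_on))
    T_c <- (T_grid[last_on] + T_grid[first_off]) / 2
  }
  list(T_c = T_c, intervals = ints, T_grid = T_grid)
}

#' Critical angle at fixed temperature
#'
#' Locates the compromise-to-decision transition angle at temperature `T`
#' two ways: the susceptibility peak over the angle grid, and the first
#' angle whose fresh-chain regime label is `decision`. A bootstrap over the
#' independent chains gives the uncertainty of the peak location.
#'
#' @param theta_grid increasing angle grid.
#' @param T temperature (should be below the estimated `T_c`).
#' @param nu,N as in [stationary_scan()].
#' @param reps independent chains per angle.
#' @param sweeps chain length per chain in units of `N` proposals.
#' @param n_boot bootstrap resamples.
#' @param seed RNG seed or `NULL`.
#' @return list with `theta_c` (susceptibility peak), `theta_c_sd`
#'   (bootstrap SD), `theta_c_label` (label-change estimate, `NA` if no
#'   decision regime on the grid), `chi` (per-angle susceptibility).
#' @export
critical_angle <- function(theta_grid, T, nu = 0.7, N = 60L, reps = 6L,
                           sweeps = 600L, n_boot = 200L, seed = NULL) {
  stopifnot(length(theta_grid) >= 3, !is.unsorted(theta_grid))
  if (!is.null(seed)) set.seed(seed)
  null_m <- null_abs_m(N)
  m_chains <- matrix(list(), length(theta_grid), reps)
  for (i in seq_along(theta_grid)) {
    for (r in seq_len(reps)) {
      net <- frozen_network(theta_grid[i], nu, N)
      ch <- metropolis(net, T, n_steps = sweeps * N, thin = N)
      m_chains[[i, r]] <- ch$m[-seq_len(length(ch$m) %/% 2)]
    }
  }
  chi_of <- function(cols) {
    vapply(seq_along(theta_grid), function(i) {
      susceptibility(unlist(m_chains[i, cols]), T, N)
    }, numeric(1))
  }
  chi <- chi_of(seq_len(reps))
  theta_c <- theta_grid[which.max(chi)]
  boot <- vapply(seq_len(n_boot), function(b) {
    cols <- sample(reps, reps, replace = TRUE)
    theta_grid[which.max(chi_of(cols))]
  }, numeric(1))
  mean_abs <- vapply(seq_along(theta_grid), function(i)
    mean(abs(unlist(m_chains[i, ]))), numeric(1))
  labs <- vapply(mean_abs, label_regime, character(1), null_m = null_m)
  first_dec <- which(labs == "decision")[1]
  list(theta_c = theta_c, theta_c_sd = sd(boot),
       theta_c_label = if (is.na(first_dec)) NA_real_
                       else theta_grid[first_dec],
       chi = chi, mean_abs_m = mean_abs, theta = theta_grid)
}
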