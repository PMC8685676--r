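# Shared helpers: tiny networks and brute-force oracles.

# Network with explicit preferred angles, k groups of equal size.
tiny_network <- function(angles, k, nu = 0.7, states = NULL) {
  n <- length(angles)
  spin_network(n, k, nu = nu, preferred_angles = angles,
               states = states %||% rep(1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exhaustive Boltzmann distribution over all 2^N states at temperature T,
# computed from the (independently evaluated) Hamiltonian. Returns the
# probability vector indexed by the binary code sum(s * 2^(i-1)) + 1.
boltzmann_exact <- function(network, T) {
  n <- network$n_spins
  states_mat <- as.matrix(expand.grid(rep(list(0:1), n)))
  H <- apply(states_mat, 1, function(s) {
    net <- network
    net$states <- as.integer(s)
    hamiltonian(net)
  })
  w <- exp(-H / T)
  list(p = w / sum(w), code = drop(states_mat %*% 2^(seq_len(n) - 1)))
}

# Frozen two-target geometry exposed for tests.
frozen2 <- function(theta, nu = 0.7, N = 8L, states = NULL) {
  spinchoice:::frozen_network(theta, nu, N, states = states)
}

# Deterministic synthetic branch-law data.
branch_data <- function(x_c, alpha, A, x = seq(0, 4, by = 0.02),
                        noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- ifelse(x <= x_c, 0, A * (x - x_c)^alpha)
  if (noise_sd > 0) y <- pmax(y + rnorm(length(x), 0, noise_sd), 0)
  list(x = x, y = y)
}
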