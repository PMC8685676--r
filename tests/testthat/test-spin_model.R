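test_that("interaction kernel matches its closed form and contracts", {
  expect_equal(interaction_strength(0, 0.7), 1)
  expect_equal(interaction_strength(pi, 1), -1)
  # (pi/4 / pi)^0.5 = 1/2 -> cos(pi/2) = 0
  expect_equal(interaction_strength(pi / 4, 0.5), 0)
  # brute-force scalar evaluation over a grid, several nu
  theta <- seq(0, pi, length.out = 41)
  for (nu in c(0.3, 0.7, 1)) {
    expect_equal(interaction_strength(theta, nu),
                 cos(pi * (theta / pi)^nu), tolerance = 1e-12)
    # endpoints pinned, strictly decreasing
    J <- interaction_strength(theta, nu)
    expect_equal(J[1], 1)
    expect_equal(J[length(J)], -1)
    expect_true(all(diff(J) < 0))
  }
  expect_error(interaction_strength(-0.5, 0.7), "theta")
  expect_error(interaction_strength(pi / 2, 0), "nu")
  expect_error(interaction_strength(pi / 2, 1.5), "nu")
})

test_that("hamiltonian matches ordered-pair sums and symmetries", {
  # all spins inactive -> 0
  net <- tiny_network(c(0, 1, 2), k = 3, states = c(0L, 0L, 0L))
  expect_equal(hamiltonian(net), 0)
  # N = 2, k = 1, both active, identical directions: H = -(1/2) * 2 = -1
  net <- tiny_network(c(0.3, 0.3), k = 1)
  expect_equal(hamiltonian(net, k = 1), -1)
  # N = 2, k = 2, both active, opposite directions, nu = 1: H = +2
  net <- tiny_network(c(0, pi), k = 2, nu = 1)
  expect_equal(hamiltonian(net), 2)
  # invariance under global rotation of all preferred directions
  set.seed(1)
  ang <- runif(6, -pi, pi)
  s <- rbinom(6, 1, 0.5)
  h0 <- hamiltonian(tiny_network(ang, k = 2, states = s))
  for (rot in c(0.5, 1.7, -2.9)) {
    h1 <- hamiltonian(tiny_network(ang + rot, k = 2, states = s))
    expect_equal(h1, h0, tolerance = 1e-10)
  }
})

test_that("consensus velocity is the normalized active resultant", {
  n <- 10
  net <- tiny_network(rep(0.4, n), k = 1)
  v <- consensus_velocity(net, v0 = 2)
  expect_equal(v, 2 * c(cos(0.4), sin(0.4)))
  net$states <- rep(0L, n)
  expect_equal(consensus_velocity(net, 1), c(0, 0))
  # two equal opposite groups cancel
  net <- tiny_network(rep(c(0, pi), each = 5), k = 2)
  expect_equal(sqrt(sum(consensus_velocity(net, 1)^2)), 0)
  # |V| <= v0 for random networks
  set.seed(2)
  for (i in 1:20) {
    net <- tiny_network(runif(12, -pi, pi), k = 2,
                        states = rbinom(12, 1, 0.5))
    expect_lte(sqrt(sum(consensus_velocity(net, 0.7)^2)), 0.7 + 1e-12)
  }
})

test_that("goal-vector refresh points at targets and carries circular noise", {
  ts <- target_set(rbind(c(1, 0), c(0, 1)))
  net <- spin_network(4, 2, preferred_angles = rep(0, 4))
  net <- refresh_goal_vectors(net, c(0, 0), ts, sigma_e = 0)
  expect_equal(net$angles, c(0, 0, pi / 2, pi / 2))
  # exact egocentric bearings from an off-origin position
  net2 <- refresh_goal_vectors(net, c(2, 2), ts, sigma_e = 0)
  expect_equal(net2$angles[1], atan2(-2, -1))
  expect_equal(net2$angles[3], atan2(-1, -2))
  # coincident with a target is an error, not a silent fallback
  expect_error(refresh_goal_vectors(net, c(1, 0), ts, 0), "coincident")
  # circular SD of the angular deviations ~ sigma_e
  big <- spin_network(1e5, 1, allocation = 1e5,
                      preferred_angles = rep(0, 1e5))
  set.seed(3)
  big <- refresh_goal_vectors(big, c(0, 0), target_set(rbind(c(1, 0))),
                              sigma_e = 0.3)
  dev <- big$angles  # true bearing is 0
  Rbar <- sqrt(mean(cos(dev))^2 + mean(sin(dev))^2)
  circ_sd <- sqrt(-2 * log(Rbar))
  expect_equal(circ_sd, 0.3, tolerance = 0.01)
})

test_that("Metropolis chain obeys the acceptance rule and Boltzmann law", {
  # a proposal lowering the energy is always accepted: at T -> 0 a
  # maximally frustrated pair relaxes to a lower-energy state
  net <- tiny_network(c(0, pi), k = 2, nu = 1)  # H = +2
  set.seed(4)
  out <- metropolis(net, T = 1e-8, n_steps = 200)
  expect_lt(hamiltonian(out$network), 2)
  # T -> 0+ freezes uphill moves: the all-aligned ground state never leaves
  net <- tiny_network(rep(0, 6), k = 1, states = rep(1L, 6))
  out <- metropolis(net, T = 1e-6, n_steps = 500)
  expect_equal(out$network$states, rep(1L, 6))

  # exhaustive-enumeration oracle: empirical state frequencies match the
  # Boltzmann distribution (TV distance below a sample-calibrated bound)
  net <- frozen2(theta = 2.0, nu = 0.7, N = 6L)
  exact <- boltzmann_exact(net, T = 0.6)
  set.seed(5)
  net$states <- rbinom(6, 1, 0.5)
  ch <- metropolis(net, T = 0.6, n_steps = 3e5, thin = 7,
                   record_states = TRUE)
  code <- drop(ch$state_trace %*% 2^(0:5))
  emp <- tabulate(match(code, exact$code), nbins = 64) / length(code)
  tv <- 0.5 * sum(abs(emp - exact$p))
  expect_lt(tv, 0.03)
})

test_that("single-target trajectories seek the target, reproducibly", {
  ts <- target_set(rbind(c(8, 3)))
  cfg <- sim_config(n_spins = 20L, T = 0.3, sigma_e = 0.1, v0 = 0.1,
                    stop_radius = 0.25, max_steps = 1500L, seed = 11)
  tr <- simulate_trajectory(ts, cfg)
  expect_equal(attr(tr, "outcome"), 1L)
  d <- sqrt((tr$x - 8)^2 + (tr$y - 3)^2)
  burn <- 20
  expect_true(all(diff(d[burn:length(d)]) < 0.1 * cfg$v0 + 1e-9))
  expect_lt(mean(diff(d[burn:length(d)])), 0)
  # bitwise reproducibility from the seed
  tr2 <- simulate_trajectory(ts, cfg)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  # speed bound per step
  step <- sqrt(diff(tr$x)^2 + diff(tr$y)^2)
  expect_true(all(step <= cfg$v0 * cfg$dt + 1e-12))
})

test_that("mirror symmetry holds over replicates", {
  ts <- make_static_geometry("two-choice", distance = 8,
                             angular_span = 40 * pi / 180)
  cfg <- sim_config(n_spins = 20L, T = 0.3, v0 = 0.1, stop_radius = 0.3,
                    max_steps = 600L)
  ens <- simulate_replicates(40, ts, cfg, base_seed = 77)
  endy <- vapply(ens, function(t) t$y[nrow(t)], numeric(1))
  # signed endpoint laterality is centred on zero within Monte-Carlo error
  expect_lt(abs(mean(sign(endy))), 2.58 * sqrt(1 / length(endy)) + 0.25)
})

test_that("network constructor enforces allocation contracts", {
  expect_error(spin_network(10, 3), "divisible")
  expect_error(spin_network(10, 2, allocation = c(7L, 2L)), "sum")
  expect_error(spin_network(4, 2, allocation = c(4L, 0L)), "at least one")
  net <- spin_network(9, 3, allocation = c(5L, 3L, 1L),
                      preferred_angles = rep(0, 9))
  expect_equal(tabulate(net$assignment), c(5L, 3L, 1L))
  # unit preferred directions by construction
  expect_equal(rowSums(preferred_dirs(net)^2), rep(1, 9))
})
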