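test_that("order parameter on states and networks", {
  net <- frozen2(1.0, N = 8L, states = rep(c(1L, 0L), each = 4L))
  expect_equal(order_parameter(net), 1)
  net$states <- rep(c(0L, 1L), each = 4L)
  expect_equal(order_parameter(net), -1)
  net$states <- rep(c(1L, 1L, 0L, 0L), 2L)
  expect_equal(order_parameter(net), 0)
  net$states <- rep(0L, 8L)
  expect_equal(order_parameter(net), 0)
  # antisymmetric under group relabelling
  s <- c(1L, 1L, 1L, 0L, 1L, 0L, 0L, 0L)
  g <- rep(1:2, each = 4L)
  expect_equal(order_parameter(s, g), -order_parameter(s, 3L - g))
})

test_that("susceptibility estimator", {
  expect_equal(susceptibility(rep(0.3, 10), T = 1, N = 10), 0)
  # alternating +/-1 has population variance exactly 1
  expect_equal(susceptibility(rep(c(-1, 1), 50), T = 1, N = 10), 10)
  expect_equal(susceptibility(rep(c(-1, 1), 50), T = 2, N = 10), 5)
  expect_error(susceptibility(1, T = 1, N = 10))
})

test_that("Monte-Carlo <|m|> matches exhaustive enumeration at N = 8", {
  net <- frozen2(theta = 2.2, nu = 0.7, N = 8L)
  exact <- boltzmann_exact(net, T = 0.5)
  states_mat <- as.matrix(expand.grid(rep(list(0:1), 8)))
  m_states <- apply(states_mat, 1, function(s) {
    n1 <- sum(s[1:4]); n2 <- sum(s[5:8])
    if (n1 + n2 == 0) 0 else (n1 - n2) / (n1 + n2)
  })
  expected <- sum(abs(m_states) * exact$p)
  set.seed(6)
  net$states <- rbinom(8, 1, 0.5)
  ch <- metropolis(net, T = 0.5, n_steps = 3e5, thin = 8)
  expect_equal(mean(abs(ch$m)), expected, tolerance = 0.03)
})

test_that("stationary scan labels the three regimes", {
  pd <- stationary_scan(theta_grid = c(0.4, 2.8), T_grid = c(0.2, 5),
                        nu = 0.7, N = 40L, reps = 3L, sweeps = 400L,
                        seed = 8)
  get <- function(th, T) pd$regime[pd$theta == th & pd$T == T]
  expect_equal(get(0.4, 0.2), "compromise")
  expect_equal(get(2.8, 0.2), "decision")
  expect_equal(get(2.8, 5), "disordered")
  expect_true(all(pd$chi >= 0))
  expect_true(all(pd$mean_abs_m >= 0 & pd$mean_abs_m <= 1))
  # <|m|> nondecreasing in theta along the low-T slice (2-point slice)
  expect_lte(pd$mean_abs_m[pd$theta == 0.4 & pd$T == 0.2],
             pd$mean_abs_m[pd$theta == 2.8 & pd$T == 0.2])
})

test_that("hysteresis interval exists at low T, empties at high T", {
  theta <- seq(1.2, 2.6, length.out = 8)
  bi_low <- detect_bistability(theta, T = 0.15, N = 60L, sweeps = 300L,
                               seed = 9)
  expect_false(is.null(bi_low$interval))
  bi_high <- detect_bistability(theta, T = 1.5, N = 60L, sweeps = 300L,
                                seed = 10)
  expect_null(bi_high$interval)
  expect_error(detect_bistability(numeric(0), T = 0.2), "empty")
})

test_that("T_c is bracketed by the hysteresis protocol", {
  theta <- seq(1.2, 2.6, length.out = 8)
  tc <- estimate_Tc(c(0.15, 0.3, 0.6, 1.2), theta, N = 60L,
                    sweeps = 300L, seed = 11)
  expect_false(is.na(tc$T_c))
  expect_gt(tc$T_c, 0.15)
  expect_lt(tc$T_c, 1.2)
})

test_that("critical angle: chi peak, mirror symmetry, label consistency", {
  theta <- seq(1.3, 2.5, length.out = 7)
  ca <- critical_angle(theta, T = 0.4, N = 40L, reps = 4L, sweeps = 400L,
                       n_boot = 50L, seed = 12)
  # mirrored geometry is the same frozen system: same estimate, same seed
  ca2 <- critical_angle(theta, T = 0.4, N = 40L, reps = 4L, sweeps = 400L,
                        n_boot = 50L, seed = 12)
  expect_equal(ca$theta_c, ca2$theta_c)
  expect_true(all(ca$chi >= 0))
  # peak and label-change estimates agree within the grid resolution
  # broadened by the bootstrap uncertainty
  expect_false(is.na(ca$theta_c_label))
  expect_lte(abs(ca$theta_c - ca$theta_c_label),
             2 * diff(theta)[1] + 2 * ca$theta_c_sd)
})
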