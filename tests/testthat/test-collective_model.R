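test_that("zonal social direction: repulsion, idle, symmetric attraction", {
  h <- c(1, 0)
  # one neighbour inside the repulsion zone at bearing b: away from it
  d <- zonal_social_direction(c(0, 0), h, rbind(c(0.5, 0)),
                              rbind(c(0, 1)), zor = 1, zoa = 8)
  expect_equal(d, c(-1, 0))
  # no neighbour in range: current heading
  d2 <- zonal_social_direction(c(0, 0), h, rbind(c(50, 50)),
                               rbind(c(0, 1)), zor = 1, zoa = 8)
  expect_equal(d2, h)
  # two attraction-zone neighbours symmetric about the heading whose
  # headings mirror each other: bisector (the heading direction itself)
  d3 <- zonal_social_direction(c(0, 0), h,
                               rbind(c(4, 3), c(4, -3)),
                               rbind(c(0, 1), c(0, -1)), 1, 8)
  expect_equal(d3, c(1, 0))
  # hand-computed vector sum: one attracting neighbour, aligned headings
  d4 <- zonal_social_direction(c(0, 0), c(0, 1), rbind(c(3, 0)),
                               rbind(c(0, 1)), 1, 8)
  v <- c(1, 0) + c(0, 1) + c(0, 1)
  expect_equal(d4, v / sqrt(sum(v^2)))
})

test_that("informed blending and omega feedback laws", {
  s <- c(1, 0); g <- c(0, 1)
  expect_equal(informed_direction(s, g, 0), s)
  expect_equal(informed_direction(s, g, 1), c(1, 1) / sqrt(2))
  expect_equal(informed_direction(s, g, 1e6), g, tolerance = 1e-5)
  # continuity in omega
  om <- seq(0, 3, by = 0.05)
  dirs <- t(vapply(om, function(w) informed_direction(s, g, w),
                   numeric(2)))
  expect_true(all(sqrt(rowSums(diff(dirs)^2)) < 0.06))
  # feedback: aligned grows, opposed decays to the floor, fixed point
  expect_gte(omega_feedback(0.4, 1, gain = 1, dt = 0.1), 0.4)
  om <- 0.6
  for (i in 1:200) om <- omega_feedback(om, -1, gain = 1, dt = 0.1)
  expect_equal(om, 0)
  expect_equal(omega_feedback(0.4, 0.5, gain = 1, dt = 0.1, c0 = 0.5),
               0.4)
  expect_lte(omega_feedback(10, 1, gain = 1, dt = 1, omega_max = 0.8),
             0.8)
})

test_that("R zonal rule agrees with the C++ simulator for one step", {
  set.seed(40)
  n <- 6
  pos <- matrix(runif(2 * n, -4, 4), n, 2)
  hd <- runif(n, -pi, pi)
  targets <- target_set(rbind(c(30, 10), c(30, -10)))
  goal <- c(0L, 0L, 1L, 1L, -1L, -1L)
  omega <- ifelse(goal >= 0, 0.5, 0)
  out <- spinchoice:::cpp_simulate_group(
    pos, hd, goal, targets$positions, speed = 1, dt = 0.05, zor = 1,
    zoa = 8, theta_max = 100, sigma_h = 0, omega0 = omega,
    omega_max = 0.8, gain = 1, c0 = 0.5, feedback = FALSE,
    stop_radius = 0.5, split_threshold = 50, split_check_every = 0,
    max_steps = 1, record_agents = TRUE)
  for (i in seq_len(n)) {
    s <- zonal_social_direction(pos[i, ], c(cos(hd[i]), sin(hd[i])),
                                pos[-i, , drop = FALSE],
                                cbind(cos(hd[-i]), sin(hd[-i])), 1, 8)
    repelled <- any(sqrt(rowSums(sweep(pos[-i, , drop = FALSE], 2,
                                       pos[i, ])^2)) <= 1)
    d <- if (goal[i] >= 0 && !repelled)  # repulsion overrides the goal
      informed_direction(s, {
        g <- targets$positions[goal[i] + 1, ] - pos[i, ]
        g / sqrt(sum(g^2))
      }, omega[i])
    else s
    want <- pos[i, ] + 1 * 0.05 * d
    got <- c(out$agent_pos[2, 2 * i - 1], out$agent_pos[2, 2 * i])
    expect_equal(got, unname(want), tolerance = 1e-10)
  }
})

test_that("split detector is deterministic single linkage", {
  chain <- cbind(seq(0, 5, by = 1), 0)  # spaced exactly 1 apart
  expect_false(split_detector(chain, threshold = 1))  # closed rule
  two <- rbind(c(0, 0), c(1, 0), c(20, 0), c(21, 0))
  expect_true(split_detector(two, threshold = 2))
  expect_false(split_detector(two, threshold = 19))
  expect_identical(split_detector(two, 2), split_detector(two, 2))
  expect_error(split_detector(rbind(c(0, 0)), 1))
})

test_that("degenerate consensus: all informed to one target", {
  targets <- target_set(rbind(c(25, 0)))
  cfg <- collective_config(n_informed_per_target = 8L, n_uninformed = 0L,
                           seed = 41)
  run <- simulate_group(targets, cfg)
  expect_equal(run$outcome, "target_1")
  # omega bounds respected
  expect_true(all(run$omega >= 0 & run$omega <= cfg$omega_max))
})

test_that("turning-rate cap is honoured by every agent at every step", {
  targets <- make_static_geometry("two-choice", distance = 30,
                                  angular_span = 40 * pi / 180)
  cfg <- collective_config(seed = 42, max_steps = 400L)
  run <- simulate_group(targets, cfg, record_agents = TRUE)
  ap <- run$agent_pos
  n <- 10
  for (i in seq_len(n)) {
    dx <- diff(ap[, 2 * i - 1]); dy <- diff(ap[, 2 * i])
    hd <- atan2(dy, dx)
    turn <- abs(spinchoice:::wrap_angle(diff(hd)))
    expect_true(all(turn <= cfg$theta_max * cfg$dt + 1e-8))
  }
})

test_that("symmetric two-target outcomes are balanced", {
  targets <- make_static_geometry("two-choice", distance = 40,
                                  angular_span = 30 * pi / 180)
  ens <- simulate_group_replicates(60, targets, collective_config(),
                                   base_seed = 43)
  oc <- attr(ens, "outcomes")
  n1 <- sum(oc == "target_1"); n2 <- sum(oc == "target_2")
  # 99% binomial interval around one half
  expect_gt(min(n1, n2) / (n1 + n2),
            0.5 - 2.58 * sqrt(0.25 / (n1 + n2)))
  # with these defaults groups essentially never split
  expect_lte(sum(oc == "split"), 3)
})
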