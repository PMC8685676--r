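test_that("rotation to the target frame is the right isometry", {
  trs <- list(data.frame(trial_id = 1, time = 0:2,
                         x = c(0, 1, 2), y = c(0, 0.5, 1)))
  # COM already on +x: identity
  sym <- rotate_to_target_frame(trs, rbind(c(5, 2), c(5, -2)))
  expect_equal(sym$trajectories[[1]]$x, trs[[1]]$x)
  expect_equal(sym$trajectories[[1]]$y, trs[[1]]$y)
  # COM at (0, d): 90 degrees clockwise; (1, 0.5) -> (0.5, -1)
  rot <- rotate_to_target_frame(trs, rbind(c(0, 3)))
  expect_equal(rot$targets, rbind(c(3, 0)), tolerance = 1e-12)
  expect_equal(rot$trajectories[[1]]$x[2], 0.5)
  expect_equal(rot$trajectories[[1]]$y[2], -1)
  # pairwise distances preserved
  tg <- rbind(c(1, 4), c(-2, 3), c(0.5, -1))
  out <- rotate_to_target_frame(trs, tg)
  expect_equal(as.numeric(dist(out$targets)), as.numeric(dist(tg)),
               tolerance = 1e-12)
  expect_error(rotate_to_target_frame(trs, tg[0, , drop = FALSE]),
               "nonempty")
})

test_that("density map bins, folds and thresholds as documented", {
  line <- list(data.frame(trial_id = 1, time = 0:100,
                          x = seq(0, 10, length.out = 101),
                          y = rep(1, 101)))
  dm <- density_map(line, xlim = c(0, 10), ylim = c(0, 2), nx = 10,
                    ny = 4, threshold = 0)
  occ <- which(dm$z > 0, arr.ind = TRUE)
  expect_true(all(dm$y_mid[occ[, 2]] > 0.5 & dm$y_mid[occ[, 2]] < 1.5))
  expect_equal(sort(unique(occ[, 1])), 1:10)
  expect_true(all(dm$z >= 0 & dm$z <= 1))

  # fold semantics: mirror-duplicating every trajectory and folding gives
  # the same map as folding the originals (weights double pre-norm)
  set.seed(13)
  tr <- data.frame(trial_id = 1, time = 0:50, x = seq(0, 5, length.out = 51),
                   y = cumsum(rnorm(51, 0, 0.2)))
  mir <- tr; mir$y <- -mir$y; mir$trial_id <- 2
  f1 <- density_map(list(tr), fold = TRUE, xlim = c(0, 5), ylim = c(0, 2),
                    nx = 20, ny = 10, threshold = 0)
  f2 <- density_map(list(tr, mir), fold = TRUE, xlim = c(0, 5),
                    ylim = c(0, 2), nx = 20, ny = 10, threshold = 0)
  expect_equal(f1$z, f2$z, tolerance = 1e-12)
  # folded maps have support only at y >= 0
  expect_true(all(f1$y_mid >= 0))
  # threshold zeroes weak cells, keeps the rest
  d_th <- density_map(list(tr), fold = TRUE, xlim = c(0, 5),
                      ylim = c(0, 2), nx = 20, ny = 10, threshold = 0.5)
  expect_true(all(d_th$z[d_th$z > 0] >= 0.5))
})

test_that("piecewise fit recovers known parameters", {
  # noiseless generation from the law itself
  d <- branch_data(1.0, 0.5, 2.0)
  f <- fit_piecewise(d$x, d$y)
  expect_equal(f$x_c, 1.0, tolerance = 1e-3)
  expect_equal(f$alpha, 0.5, tolerance = 1e-3)
  expect_equal(f$A, 2.0, tolerance = 1e-3)
  expect_false(f$unidentifiable)
  # linear ramp: closed-form case
  x <- seq(0, 4, by = 0.05)
  f2 <- fit_piecewise(x, pmax(0, x - 2))
  expect_equal(f2$x_c, 2, tolerance = 1e-2)
  expect_equal(f2$alpha, 1, tolerance = 1e-2)
  expect_equal(f2$A, 1, tolerance = 1e-2)
  # flat data: explicit unidentifiable status
  f3 <- fit_piecewise(x, rep(0, length(x)))
  expect_true(f3$unidentifiable)
  expect_equal(f3$A, 0)
  expect_true(is.na(f3$x_c))
  # deterministic given inputs
  d2 <- branch_data(1.5, 0.8, 1.2, noise_sd = 0.05, seed = 21)
  expect_identical(fit_piecewise(d2$x, d2$y)[c("x_c", "alpha", "A")],
                   fit_piecewise(d2$x, d2$y)[c("x_c", "alpha", "A")])
  expect_error(fit_piecewise(1:3, c(0, 1, 2)), "4")
  expect_error(fit_piecewise(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("piecewise fit calibration: 10% noise, <10% median error", {
  set.seed(22)
  rel_err <- t(replicate(100, {
    x_c <- runif(1, 0.5, 2); alpha <- runif(1, 0.3, 1.5)
    A <- runif(1, 0.5, 3)
    ymax <- A * (4 - x_c)^alpha
    d <- branch_data(x_c, alpha, A, noise_sd = 0.1 * ymax)
    f <- fit_piecewise(d$x, d$y)
    c(abs(f$x_c - x_c) / x_c, abs(f$alpha - alpha) / alpha)
  }))
  expect_lt(median(rel_err[, 1]), 0.10)
  expect_lt(median(rel_err[, 2]), 0.10)
})

test_that("randomization test p-values and schemes", {
  fx <- fixture_generator(31, n_tracks = 24)
  # observed statistic above every permuted value: p = 1/(1+n_perm)
  rt <- randomization_test(fx$bifurcating, n_perm = 99, seed = 1)
  expect_equal(rt$p, 0.01)
  expect_gt(rt$observed, max(rt$permuted))
  # the trajectory-level scheme is available and returns a valid p
  rt2 <- randomization_test(fx$bifurcating, n_perm = 19,
                            scheme = "trajectory", seed = 2)
  expect_true(rt2$p >= 1 / 20 && rt2$p <= 1)
  # custom statistic: amplitude A
  rtA <- randomization_test(fx$bifurcating, n_perm = 19, seed = 3,
                            statistic = function(trs)
                              bifurcation_amplitude(trs)$A)
  expect_true(is.finite(rtA$observed))
  expect_error(randomization_test(fx$bifurcating, n_perm = 5), "19")
})

test_that("randomization test is calibrated on pre-shuffled ensembles", {
  fx <- fixture_generator(32, n_tracks = 20)
  trs <- fx$bifurcating
  lens <- vapply(trs, nrow, integer(1))
  pool <- unlist(lapply(trs, `[[`, "y"))
  set.seed(33)
  ps <- replicate(30, {
    yp <- split(pool[sample.int(length(pool))],
                rep(seq_along(trs), lens))
    null_ens <- Map(function(tr, y) { tr$y <- y; tr }, trs, yp)
    randomization_test(null_ens, n_perm = 19)$p
  })
  # type-I error at most nominal (binomial slack for 30 draws)
  expect_lte(mean(ps <= 0.05), 0.05 + 2.58 * sqrt(0.05 * 0.95 / 30))
  # p spreads over its attainable grid rather than sticking to one value
  expect_gt(length(unique(ps)), 5)
})

test_that("track classification follows the declared rules", {
  fx <- fixture_generator(34)
  lbl <- classify_track(fx$straight)
  expect_equal(lbl$label, "direct")
  # 60% zero-displacement steps with wander_fraction 0.5 -> wandering
  tr <- data.frame(trial_id = 1, time = 0:99,
                   x = cumsum(c(0, rep(c(0.1, 0, 0, 0, 0.1), 19), 0.1,
                                0, 0, 0)),
                   y = 0)
  attr(tr, "outcome") <- NA_integer_
  wl <- classify_track(tr, targets = target_set(rbind(c(100, 0))),
                       v0 = 0.1)
  expect_equal(wl$label, "wandering")
  expect_gte(wl$stationary_fraction, 0.5)
  # bisector-then-turn trajectory from the model is nondirect
  ts <- make_static_geometry("two-choice", distance = 8,
                             angular_span = 60 * pi / 180)
  cfg <- sim_config(n_spins = 20L, T = 0.25, v0 = 0.1, stop_radius = 0.3,
                    max_steps = 800L, seed = 35)
  sim <- simulate_trajectory(ts, cfg)
  expect_false(is.na(attr(sim, "outcome")))
  expect_equal(classify_track(sim)$label, "nondirect")
})

test_that("heading profile deviations", {
  tg <- rbind(c(10, 5), c(10, -5))
  # motion along the bisector: zero deviation from the average direction
  tr <- data.frame(trial_id = 1, time = 0:20,
                   x = seq(0, 2, length.out = 21), y = 0)
  hp <- heading_profile(tr, tg)
  expect_equal(max(abs(hp$dev_avg)), 0, tolerance = 1e-12)
  # motion straight at target 1: zero deviation from that bearing
  b <- atan2(5, 10)
  tr2 <- data.frame(trial_id = 1, time = 0:20,
                    x = seq(0, 2, length.out = 21) * cos(b),
                    y = seq(0, 2, length.out = 21) * sin(b))
  hp2 <- heading_profile(tr2, tg)
  expect_equal(max(abs(hp2$dev_target_1)), 0, tolerance = 1e-10)
  expect_true(all(hp2$heading > -pi & hp2$heading <= pi))
})

test_that("pre-bifurcation headings track the average direction", {
  p <- scenario_preset("two-choice")
  ens <- simulate_replicates(30, p$targets, p$config, base_seed = 36)
  amp <- bifurcation_amplitude(lapply(ens, as.data.frame))
  xc <- amp$fit$x_c
  devs <- do.call(rbind, lapply(ens, function(tr) {
    hp <- heading_profile(as.data.frame(tr), attr(tr, "targets")$positions)
    pre <- tr$x[-nrow(tr)] < xc - 1 & tr$x[-nrow(tr)] > 1
    hp[pre, c("dev_avg", "dev_target_1", "dev_target_2")]
  }))
  # compromise phase: closer to the average direction than to either
  # single-target bearing, no alternating fixation
  expect_lt(mean(abs(devs$dev_avg)), mean(abs(devs$dev_target_1)))
  expect_lt(mean(abs(devs$dev_avg)), mean(abs(devs$dev_target_2)))
})

test_that("moving-frame offsets and marginals", {
  # constant lateral offset -> point mass at that offset
  tg <- make_moving_geometry(0.06, speed = 0.004, bounds = c(-0.3, 0.3))
  cfg <- sim_config(n_spins = 20L, T = 0.25, v0 = 0.01, stop_radius = 0,
                    max_steps = 50L, start = c(-0.1, 0.018), seed = 37)
  tr <- simulate_trajectory(tg, cfg, record_targets = TRUE)
  # fabricate a constant-offset follower against the recorded targets
  tr$y <- rep(0.018, nrow(tr))
  lat <- lateral_offsets(tr, drop_first = 0)
  expect_true(all(abs(lat - 0.018) < 1e-12))
  # marginal rows are normalized to max 1
  ens <- structure(list(tr), class = "trajectory_ensemble")
  mm <- moving_frame_marginals(list(ens), 0.06,
                               breaks = seq(-0.1, 0.1, 0.005),
                               drop_first = 0)
  expect_equal(max(mm[1, ]), 1)
  expect_equal(which.max(mm[1, ]),
               which.min(abs(attr(mm, "mids") - 0.018)))
})

test_that("lateral mode finder", {
  set.seed(38)
  x <- c(rnorm(4000, -0.04, 0.008), rnorm(3000, 0.04, 0.008))
  m <- lateral_modes(x, binwidth = 0.005)
  expect_equal(length(m$modes), 2L)
  expect_equal(m$modes[1], -0.04, tolerance = 0.006)
  expect_equal(m$modes[2], 0.04, tolerance = 0.006)
  expect_equal(m$half_separation, 0.04, tolerance = 0.006)
  # unimodal data yields one mode and NA separation
  m1 <- lateral_modes(rnorm(5000, 0, 0.01), binwidth = 0.005)
  expect_true(is.na(m1$half_separation))
})
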