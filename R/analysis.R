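#' Rotate trajectories into the target frame
#'
#' Rotates every trajectory (and the targets) about `origin` so that the
#' center of mass of the targets lies on the positive x-axis. A pure
#' rotation: all pairwise distances are preserved.
#'
#' @param trajectories list of trajectory data frames (columns `x`, `y`).
#' @param targets a [target_set()] or a k x 2 position matrix.
#' @param origin rotation center (default the conventional start, the
#'   origin).
#' @return list with rotated `trajectories` and `targets` (matrix), plus
#'   the applied `angle`.
#' @export
rotate_to_target_frame <- function(trajectories, targets,
                                   origin = c(0, 0)) {
  pos <- if (inherits(targets, "target_set")) targets$positions
         else as.matrix(targets)
  if (nrow(pos) < 1) stop("targets must be nonempty")
  com <- colMeans(pos) - origin
  ang <- atan2(com[2], com[1])
  R <- matrix(c(cos(-ang), sin(-ang), -sin(-ang), cos(-ang)), 2, 2)
  rot <- function(m) sweep(sweep(m, 2, origin) %*% t(R), 2, origin, "+")
  trs <- lapply(trajectories, function(d) {
    xy <- rot(cbind(d$x, d$y))
    d$x <- xy[, 1]; d$y <- xy[, 2]
    d
  })
  list(trajectories = trs, targets = rot(pos), angle = ang)
}

#' Time-normalized trajectory density map
#'
#' Each trajectory's time is normalized to `[0, 1]`; a window of width
#' `window` slides over normalized time in half-window steps. Per window
#' the pooled positions are binned on the grid, optionally folded about
#' `y = 0` (weight at `(x, -y)` added into `(x, y)`), and the histogram is
#' scaled to a maximum of 1. Windows are combined cell-wise by maximum, and
#' cells below `threshold` (relative to the map maximum of 1) are zeroed.
#' The per-window normalization equalizes the footprint of slow and fast
#' trajectory phases.
#'
#' @param trajectories list of trajectory data frames (columns `time`,
#'   `x`, `y`), or a single long data frame with `trial_id`.
#' @param xlim,ylim grid extent; defaults to the data range.
#' @param nx,ny number of bins.
#' @param window sliding-window width in normalized time.
#' @param fold fold about the symmetry line `y = 0`.
#' @param threshold relative density threshold (0 removes nothing).
#' @return an object of class `density_map`: list with matrix `z`
#'   (`nx` x `ny`, values in `[0, 1]`), bin centers `x_mid`, `y_mid`, bin
#'   edges, and the settings used.
#' @export
density_map <- function(trajectories, xlim = NULL, ylim = NULL,
                        nx = 100L, ny = 80L, window = 0.05,
                        fold = FALSE, threshold = 0.1) {
  if (is.data.frame(trajectories))
    trajectories <- split(trajectories, trajectories$trial_id)
  pts <- do.call(rbind, lapply(trajectories, function(d)
    data.frame(tn = normalized_time(d$time), x = d$x, y = d$y)))
  if (is.null(xlim)) xlim <- range(pts$x)
  if (is.null(ylim)) ylim <- if (fold) c(0, max(abs(pts$y))) else range(pts$y)
  if (fold) { pts$y <- abs(pts$y); ylim[1] <- max(ylim[1], 0) }
  xb <- seq(xlim[1], xlim[2], length.out = nx + 1L)
  yb <- seq(ylim[1], ylim[2], length.out = ny + 1L)
  starts <- seq(0, max(0, 1 - window), by = window / 2)
  z <- matrix(0, nx, ny)
  for (s in starts) {
    sel <- pts$tn >= s & pts$tn <= s + window
    if (!any(sel)) next
    h <- bin2d(pts$x[sel], pts$y[sel], xb, yb)
    mx <- max(h)
    if (mx > 0) z <- pmax(z, h / mx)
  }
  if (threshold > 0) z[z < threshold] <- 0
  structure(list(z = z,
                 x_mid = (xb[-1] + xb[-length(xb)]) / 2,
                 y_mid = (yb[-1] + yb[-length(yb)]) / 2,
                 x_breaks = xb, y_breaks = yb, window = window,
                 fold = fold, threshold = threshold),
            class = "density_map")
}

# 2-D histogram on fixed edges; out-of-range points are dropped.
bin2d <- function(x, y, xb, yb) {
  keep <- x >= xb[1] & x <= xb[length(xb)] &
    y >= yb[1] & y <= yb[length(yb)]
  x <- x[keep]; y <- y[keep]
  nx <- length(xb) - 1L; ny <- length(yb) - 1L
  if (!length(x)) return(matrix(0, nx, ny))
  ix <- pmin(pmax(findInterval(x, xb, rightmost.closed = TRUE), 1L), nx)
  iy <- pmin(pmax(findInterval(y, yb, rightmost.closed = TRUE), 1L), ny)
  h <- matrix(0, nx, ny)
  tab <- table(factor(ix, levels = seq_len(nx)),
               factor(iy, levels = seq_len(ny)))
  h[] <- as.numeric(tab)
  h
}

#' Surviving cells of a density map as weighted points
#'
#' @param map a [density_map()].
#' @return data frame with columns `x`, `y` (cell centers) and `w` (cell
#'   value), for cells with positive density.
#' @export
map_points <- function(map) {
  stopifnot(inherits(map, "density_map"))
  idx <- which(map$z > 0, arr.ind = TRUE)
  data.frame(x = map$x_mid[idx[, 1]], y = map$y_mid[idx[, 2]],
             w = map$z[idx])
}

#' @export
plot.density_map <- function(x, fit = NULL, ...) {
  graphics::image(x$x_mid, x$y_mid, x$z, xlab = "x", ylab = "y",
                  col = grDevices::hcl.colors(32, "YlOrRd", rev = TRUE),
                  ...)
  if (!is.null(fit) && !fit$unidentifiable)
    graphics::curve(fit$fitted(x), add = TRUE, lwd = 2)
  invisible(x)
}

#' Classify a track as direct, nondirect or wandering
#'
#' A captured track is `direct` when its travel time does not exceed
#' `direct_time_factor` times the straight-line time (start-to-target
#' distance over `v0`); a track whose fraction of near-zero displacement
#' steps is at least `wander_fraction` is `wandering`; everything else is
#' `nondirect`. Checks are applied in that order.
#'
#' @param trajectory a `spin_trajectory` (or data frame with `time`, `x`,
#'   `y` plus an `outcome` attribute).
#' @param targets a [target_set()]; defaults to the one stored on the
#'   trajectory.
#' @param v0 nominal speed; defaults to the stored configuration's.
#' @param direct_time_factor multiple of the straight-line time that still
#'   counts as direct.
#' @param wander_fraction stationary-step fraction labeling a wanderer.
#' @param stationary_frac step displacement below `stationary_frac * v0 *
#'   dt` counts as stationary.
#' @return list of class `track_label`: `label` (one of `"direct"`,
#'   `"nondirect"`, `"wandering"`), `time_to_target`, `straightline_time`,
#'   `stationary_fraction`.
#' @export
classify_track <- function(trajectory, targets = attr(trajectory, "targets"),
                           v0 = NULL, direct_time_factor = 1.5,
                           wander_fraction = 0.5, stationary_frac = 0.1) {
  cfg <- attr(trajectory, "config")
  if (is.null(v0)) v0 <- cfg$v0 %||% stop("`v0` required")
  dt <- cfg$dt %||% diff(trajectory$time[1:2])
  outcome <- attr(trajectory, "outcome")
  n <- nrow(trajectory)
  step <- sqrt(diff(trajectory$x)^2 + diff(trajectory$y)^2)
  stat_frac <- mean(step < stationary_frac * v0 * dt)
  t_total <- trajectory$time[n] - trajectory$time[1]
  sl_time <- NA_real_
  label <- NA_character_
  if (!is.null(outcome) && !is.na(outcome)) {
    tp <- target_positions(targets)[outcome, ]
    d0 <- sqrt(sum((c(trajectory$x[1], trajectory$y[1]) - tp)^2))
    sl_time <- d0 / v0
    if (t_total <= direct_time_factor * sl_time) label <- "direct"
  }
  if (is.na(label))
    label <- if (stat_frac >= wander_fraction) "wandering" else "nondirect"
  structure(list(label = label, time_to_target = t_total,
                 straightline_time = sl_time,
                 stationary_fraction = stat_frac),
            class = "track_label")
}

#' Heading profile relative to the targets
#'
#' Per movement step: the movement heading, its deviation from the bearing
#' to each target, and its deviation from the average target direction
#' (circular mean of the per-target bearings). All angles wrapped to
#' `(-pi, pi]`.
#'
#' @param trajectory data frame with `time`, `x`, `y` (>= 2 rows).
#' @param targets a [target_set()] or k x 2 matrix (static positions).
#' @return data frame with columns `time`, `heading`, `dev_avg` and
#'   `dev_target_<j>` for each target.
#' @export
heading_profile <- function(trajectory, targets) {
  stopifnot(nrow(trajectory) >= 2)
  pos <- if (inherits(targets, "target_set")) targets$positions
         else as.matrix(targets)
  n <- nrow(trajectory) - 1L
  hx <- diff(trajectory$x); hy <- diff(trajectory$y)
  heading <- atan2(hy, hx)
  px <- trajectory$x[seq_len(n)]; py <- trajectory$y[seq_len(n)]
  devs <- sapply(seq_len(nrow(pos)), function(j) {
    b <- atan2(pos[j, 2] - py, pos[j, 1] - px)
    wrap_angle(heading - b)
  })
  bearings <- sapply(seq_len(nrow(pos)), function(j)
    atan2(pos[j, 2] - py, pos[j, 1] - px))
  avg <- atan2(rowMeans(sin(bearings)), rowMeans(cos(bearings)))
  out <- data.frame(time = trajectory$time[seq_len(n)], heading = heading,
                    dev_avg = wrap_angle(heading - avg))
  colnames(devs) <- paste0("dev_target_", seq_len(nrow(pos)))
  cbind(out, devs)
}

#' Lateral offsets of a follower in the targets' moving frame
#'
#' For a trajectory recorded against moving targets, returns the follower's
#' position along the axis perpendicular to the travel axis, measured from
#' the targets' lateral center (midpoint of the outermost movers), keeping
#' only following episodes: steps at which the follower is behind the
#' target centroid along the current direction of travel.
#'
#' @param trajectory a `spin_trajectory` simulated with
#'   `record_targets = TRUE` against a moving [target_set()].
#' @param drop_first number of initial steps discarded as approach
#'   transient.
#' @return numeric vector of lateral offsets (one per retained step), with
#'   attribute `n_episodes` (number of contiguous following episodes).
#' @export
lateral_offsets <- function(trajectory, drop_first = 200L) {
  tp <- attr(trajectory, "target_pos")
  tdir <- attr(trajectory, "target_dir")
  targets <- attr(trajectory, "targets")
  if (is.null(tp) || is.null(targets$motion))
    stop("trajectory must be simulated against moving targets with ",
         "record_targets = TRUE")
  axis <- targets$motion$axis
  perp <- c(-axis[2], axis[1])
  k <- targets$k
  xs <- tp[, 2 * seq_len(k) - 1, drop = FALSE]
  ys <- tp[, 2 * seq_len(k), drop = FALSE]
  cx <- rowMeans(xs); cy <- rowMeans(ys)
  lat_t <- xs * perp[1] + ys * perp[2]  # per-target lateral coordinate
  lat_center <- (apply(lat_t, 1, max) + apply(lat_t, 1, min)) / 2
  along <- (trajectory$x - cx) * axis[1] + (trajectory$y - cy) * axis[2]
  lat <- trajectory$x * perp[1] + trajectory$y * perp[2] - lat_center
  behind <- along * tdir < 0
  keep <- behind & seq_along(behind) > drop_first
  runs <- rle(keep)
  structure(lat[keep],
            n_episodes = sum(runs$values & runs$lengths >= 10))
}

#' Stacked moving-frame marginal distributions
#'
#' For a set of follower ensembles simulated at different lateral spacings
#' `L`, pools the following-episode lateral offsets per ensemble, bins them
#' on a common grid, scales every row to a maximum of 1, and stacks the
#' rows (one per `L`).
#'
#' @param ensembles named list: one `trajectory_ensemble` (moving targets,
#'   recorded) per lateral spacing.
#' @param L_values numeric vector of spacings, same length as `ensembles`.
#' @param breaks histogram breaks for the lateral coordinate.
#' @param drop_first see [lateral_offsets()].
#' @return matrix (length(L) x bins) of normalized marginals, with
#'   attributes `L` and `mids`.
#' @export
moving_frame_marginals <- function(ensembles, L_values,
                                   breaks = seq(-0.25, 0.25, by = 0.005),
                                   drop_first = 200L) {
  stopifnot(length(ensembles) == length(L_values))
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  out <- t(vapply(ensembles, function(ens) {
    lat <- unlist(lapply(ens, lateral_offsets, drop_first = drop_first))
    h <- graphics::hist(lat[lat >= breaks[1] & lat <= breaks[length(breaks)]],
                        breaks = breaks, plot = FALSE)$counts
    if (max(h) > 0) h / max(h) else h
  }, numeric(length(mids))))
  attr(out, "L") <- L_values
  attr(out, "mids") <- mids
  out
}

#' Locate the two modes of a lateral-position distribution
#'
#' Histograms the offsets at `binwidth` (bins aligned on zero) and returns
#' the two highest raw-count local maxima separated by at least `min_sep`
#' bins. No smoothing: the mode is the literal peak bin of the histogram
#' at the stated bin width.
#'
#' @param offsets numeric vector of lateral offsets.
#' @param binwidth histogram bin width.
#' @param min_sep minimum mode separation in bins (guards against reading
#'   two bins of one broad peak as distinct modes).
#' @return list with `modes` (sorted bin centers, length 2, or length 1 if
#'   no second qualifying peak exists), `half_separation`
#'   (`diff(modes) / 2`, `NA` if unimodal), `counts`, `mids`.
#' @export
lateral_modes <- function(offsets, binwidth = 0.005, min_sep = 6L) {
  lo <- floor(min(offsets) / binwidth) * binwidth
  hi <- ceiling(max(offsets) / binwidth) * binwidth
  breaks <- seq(lo - binwidth / 2, hi + binwidth / 2, by = binwidth)
  h <- graphics::hist(offsets, breaks = breaks, plot = FALSE)
  cnt <- h$counts
  n <- length(cnt)
  is_peak <- vapply(seq_len(n), function(i) {
    l <- if (i > 1) cnt[i - 1] else -Inf
    r <- if (i < n) cnt[i + 1] else -Inf
    cnt[i] > 0 && cnt[i] >= l && cnt[i] >= r && (cnt[i] > l || cnt[i] > r)
  }, logical(1))
  peaks <- which(is_peak)
  peaks <- peaks[order(cnt[peaks], decreasing = TRUE)]
  sel <- integer(0)
  for (p in peaks) {
    if (all(abs(p - sel) >= min_sep)) sel <- c(sel, p)
    if (length(sel) == 2L) break
  }
  modes <- sort(h$mids[sel])
  list(modes = modes,
       half_separation = if (length(modes) == 2L) diff(modes) / 2
                         else NA_real_,
       counts = cnt, mids = h$mids)
}

#' Per-target elimination times along a trajectory
#'
#' Scans the stored per-target activity fractions and reports, for each
#' target, the movement step at which its (smoothed) active fraction drops
#' below `lo` for good — i.e. the step after the last time it exceeded
#' `lo` — provided at least `persist` steps remain, the group stays
#' suppressed, and some other target's activity exceeds `hi` at that
#' moment (the signature of the network spontaneously eliminating an
#' option rather than a transient dip).
#'
#' @param trajectory a `spin_trajectory`.
#' @param lo activity fraction below which a target counts as eliminated.
#' @param hi activity another target must exceed at the elimination step.
#' @param persist minimum number of suppressed steps remaining before
#'   capture for the elimination to count.
#' @param smooth running-mean window (steps) applied to the activity.
#' @return data frame with columns `target`, `step` (`NA` if never
#'   eliminated), `x`, `y` (agent position at elimination).
#' @export
eliminations <- function(trajectory, lo = 0.2, hi = 0.6, persist = 10L,
                         smooth = 11L) {
  ga <- attr(trajectory, "group_activity")
  if (is.null(ga)) stop("trajectory lacks group activity; simulate with ",
                        "the package simulator")
  k <- ncol(ga)
  n <- nrow(ga)
  sm <- apply(ga, 2, function(v) {
    s <- as.numeric(stats::filter(v, rep(1 / smooth, smooth), sides = 2))
    s[is.na(s)] <- v[is.na(s)]
    s
  })
  other_hi <- vapply(seq_len(n), function(i) max(sm[i, ]), numeric(1))
  out <- lapply(seq_len(k), function(g) {
    above <- which(sm[, g] >= lo)
    step <- if (length(above) == 0L) 1L
            else if (max(above) <= n - persist) max(above) + 1L
            else NA_integer_
    if (!is.na(step) && other_hi[step] <= hi) step <- NA_integer_
    data.frame(target = g, step = step,
               x = if (is.na(step)) NA_real_ else trajectory$x[step],
               y = if (is.na(step)) NA_real_ else trajectory$y[step])
  })
  do.call(rbind, out)
}

#' Re-fit the second decision stage of a three-target ensemble
#'
#' After the first elimination removes an outermost target, the remaining
#' two options define a fresh two-choice problem. This helper standardizes
#' every qualifying trajectory (reflecting trials whose first elimination
#' removed the upper outer target so all first eliminations remove the
#' lower one), truncates it to the samples after its first elimination,
#' and rotates the frame about the mean first-branch point so the bisector
#' of the two remaining targets points along +x. The folded density of the
#' transformed segments is then fit with the piecewise branch law: a
#' positive amplitude is the second bifurcation.
#'
#' @param ensemble a `trajectory_ensemble` from the symmetric three-choice
#'   geometry (outer targets first and last, center in between).
#' @param ... passed to [eliminations()].
#' @return list with `fit` (a [fit_piecewise()] result in the rotated
#'   frame), `r2`, `segments` (transformed trajectory list), `branch_point`
#'   (mean first-elimination position), `outcome_split` (table of final
#'   outcomes among used trials).
#' @export
refit_second_stage <- function(ensemble, ...) {
  targets <- attr(ensemble, "targets")
  stopifnot(targets$k == 3L)
  outer_lo <- 1L; outer_hi <- 3L; center <- 2L
  segs <- list(); bp <- NULL; outs <- integer(0)
  for (tr in ensemble) {
    e <- eliminations(tr, ...)
    e <- e[!is.na(e$step), , drop = FALSE]
    e <- e[order(e$step), , drop = FALSE]
    if (nrow(e) < 1L || !(e$target[1] %in% c(outer_lo, outer_hi))) next
    d <- as.data.frame(tr)[, c("trial_id", "time", "x", "y")]
    oc <- attr(tr, "outcome")
    if (e$target[1] == outer_hi) {  # standardize: reflect about y = 0
      d$y <- -d$y
      oc <- if (!is.na(oc)) c(3L, 2L, 1L)[oc] else oc
    }
    step1 <- e$step[1]
    if (step1 >= nrow(d) - 5L) next
    segs[[length(segs) + 1L]] <- d[step1:nrow(d), , drop = FALSE]
    bp <- rbind(bp, c(d$x[step1], d$y[step1]))
    outs <- c(outs, oc)
  }
  if (length(segs) < 5L)
    stop("too few trajectories with a detected first elimination")
  branch_point <- colMeans(bp)
  # remaining options after standardization: center (2) and upper outer (3)
  pos <- targets$positions[c(center, outer_hi), , drop = FALSE]
  b <- atan2(pos[, 2] - branch_point[2], pos[, 1] - branch_point[1])
  bis <- atan2(mean(sin(b)), mean(cos(b)))
  R <- matrix(c(cos(-bis), sin(-bis), -sin(-bis), cos(-bis)), 2, 2)
  segs <- lapply(seq_along(segs), function(i) {
    d <- segs[[i]]
    xy <- sweep(cbind(d$x, d$y), 2, branch_point) %*% t(R)
    data.frame(trial_id = i, time = d$time, x = xy[, 1], y = xy[, 2])
  })
  amp <- bifurcation_amplitude(segs)
  list(fit = amp$fit, r2 = amp$r2, segments = segs,
       branch_point = branch_point,
       outcome_split = table(factor(outs, levels = 1:3)))
}

#' Sequential-bifurcation summary of a multi-target ensemble
#'
#' Aggregates [eliminations()] over an ensemble: for every trajectory the
#' targets are ranked by elimination time; the summary reports how often
#' the first-eliminated target is an outermost one, and the mean agent
#' x-position at the first and second elimination (the spatial branch
#' points).
#'
#' @param ensemble a `trajectory_ensemble` from a k >= 3 geometry.
#' @param outer indices of the outermost targets (default first and last).
#' @param ... passed to [eliminations()].
#' @return list with `first_outer_fraction`, `branch_x` (mean x at first
#'   and second elimination), `branch_x_sd`, `n_used` (trajectories with
#'   two detected eliminations), and the per-trajectory `detail`.
#' @export
sequential_bifurcation <- function(ensemble,
                                   outer = c(1L, attr(ensemble,
                                                      "targets")$k),
                                   ...) {
  det <- lapply(ensemble, function(tr) {
    e <- eliminations(tr, ...)
    e <- e[!is.na(e$step), , drop = FALSE]
    e[order(e$step), , drop = FALSE]
  })
  two <- vapply(det, nrow, integer(1)) >= 2L
  first <- vapply(det[two], function(e) e$target[1], integer(1))
  x1 <- vapply(det[two], function(e) e$x[1], numeric(1))
  x2 <- vapply(det[two], function(e) e$x[2], numeric(1))
  list(first_outer_fraction = if (any(two)) mean(first %in% outer)
                              else NA_real_,
       branch_x = c(first = mean(x1), second = mean(x2)),
       branch_x_sd = c(first = sd(x1), second = sd(x2)),
       n_used = sum(two), detail = det)
}
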