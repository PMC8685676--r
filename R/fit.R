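#' Piecewise critical-point fit
#'
#' Fits the branch-opening function
#' \deqn{y = 0 \;(x \le x_c), \qquad y = A |x - x_c|^\alpha \;(x > x_c)}
#' to nonnegative data by weighted least squares. `x_c` is profiled over a
#' grid (then refined by golden-section search), `alpha` is optimized
#' numerically for each candidate `x_c`, and `A` has a closed-form weighted
#' least-squares solution given the other two. Deterministic given the data
#' and the grid specification.
#'
#' @param x,y numeric vectors (`y >= 0`), at least 4 points with
#'   nondegenerate `x` spread.
#' @param weights optional nonnegative weights (default 1).
#' @param n_xc number of candidate break points.
#' @param xc_range range searched for `x_c` (default: data range, excluding
#'   the top 5% so at least some points lie beyond the break).
#' @param alpha_range interval searched for the exponent.
#' @return an object of class `piecewise_fit`: list with `x_c`, `alpha`,
#'   `A`, `rss`, `unidentifiable` (TRUE when `y` is essentially all zero,
#'   in which case `A = 0` and `x_c` is `NA`), and `fitted` (function of x).
#' @examples
#' x <- seq(0, 4, by = 0.05)
#' y <- pmax(0, x - 2)           # x_c = 2, alpha = 1, A = 1
#' f <- fit_piecewise(x, y)
#' c(f$x_c, f$alpha, f$A)
#' @export
fit_piecewise <- function(x, y, weights = NULL, n_xc = 40L,
                          xc_range = NULL, alpha_range = c(0.05, 3)) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (diff(range(x)) <= 0) stop("x spread is degenerate")
  if (any(y < 0)) stop("y must be nonnegative")
  w <- if (is.null(weights)) rep(1, length(x)) else weights
  stopifnot(length(w) == length(x), all(w >= 0), any(w > 0))

  if (max(y[w > 0]) <= 1e-12 * max(1, diff(range(x)))) {
    return(structure(list(x_c = NA_real_, alpha = NA_real_, A = 0,
                          rss = 0, unidentifiable = TRUE,
                          fitted = function(xx) rep(0, length(xx))),
                     class = "piecewise_fit"))
  }

  if (is.null(xc_range))
    xc_range <- c(min(x), quantile(x, 0.95, names = FALSE))
  rss_at <- function(xc) {
    right <- x > xc
    base <- sum(w[!right] * y[!right]^2)
    if (!any(right)) return(list(rss = base + sum(w[right] * y[right]^2),
                                 alpha = NA_real_, A = 0))
    xr <- x[right] - xc; yr <- y[right]; wr <- w[right]
    obj <- function(alpha) {
      g <- xr^alpha
      A <- sum(wr * yr * g) / sum(wr * g^2)
      A <- max(A, 0)
      sum(wr * (yr - A * g)^2)
    }
    op <- optimize(obj, alpha_range)
    g <- xr^op$minimum
    A <- max(sum(wr * yr * g) / sum(wr * g^2), 0)
    list(rss = base + op$objective, alpha = op$minimum, A = A)
  }
  xc_grid <- seq(xc_range[1], xc_range[2], length.out = n_xc)
  rss_grid <- vapply(xc_grid, function(xc) rss_at(xc)$rss, numeric(1))
  i <- which.min(rss_grid)
  lo <- xc_grid[max(1L, i - 1L)]; hi <- xc_grid[min(n_xc, i + 1L)]
  xc <- if (hi > lo)
    optimize(function(xc) rss_at(xc)$rss, c(lo, hi))$minimum
  else xc_grid[i]
  best <- rss_at(xc)
  structure(list(x_c = xc, alpha = best$alpha, A = best$A, rss = best$rss,
                 unidentifiable = FALSE,
                 fitted = local({
                   xc0 <- xc; a0 <- best$alpha; A0 <- best$A
                   function(xx) ifelse(xx <= xc0, 0, A0 * (xx - xc0)^a0)
                 })),
            class = "piecewise_fit")
}

#' @export
print.piecewise_fit <- function(x, ...) {
  if (x$unidentifiable)
    cat("<piecewise_fit> flat data: A = 0, x_c unidentifiable\n")
  else
    cat(sprintf("<piecewise_fit> x_c = %.4g, alpha = %.4g, A = %.4g (rss %.4g)\n",
                x$x_c, x$alpha, x$A, x$rss))
  invisible(x)
}

#' Bifurcation amplitude of a trajectory ensemble
#'
#' The default test statistic for [randomization_test()]: build a folded,
#' time-normalized density map of the ensemble and return the amplitude `A`
#' of the piecewise critical-point fit to the surviving cells (cell centers
#' weighted by cell density).
#'
#' @param trajectories list of trajectory data frames (columns `time`,
#'   `x`, `y`).
#' @param map_args arguments passed to [density_map()] (`fold` is forced
#'   `TRUE`).
#' @param fit_args arguments passed to [fit_piecewise()].
#' @return list with the scalar amplitude `A`, the weighted fit quality
#'   `r2` (1 - rss / weighted total sum of squares), the full `fit` and
#'   the `map`.
#' @export
bifurcation_amplitude <- function(trajectories, map_args = list(),
                                  fit_args = list()) {
  map_args$fold <- TRUE
  dm <- do.call(density_map, c(list(trajectories), map_args))
  pts <- map_points(dm)
  fit <- do.call(fit_piecewise,
                 c(list(x = pts$x, y = pts$y, weights = pts$w), fit_args))
  tss <- sum(pts$w * (pts$y - sum(pts$w * pts$y) / sum(pts$w))^2)
  list(A = fit$A, r2 = if (tss > 0) 1 - fit$rss / tss else 0,
       fit = fit, map = dm)
}

#' y-swap randomization test
#'
#' Permutation null for trajectory bifurcations: every permuted ensemble
#' keeps each trial's `x` (and time) series and substitutes its `y`
#' values with y values from other random events. Two schemes are
#' provided. `"pointwise"` (default) permutes the pooled y values across
#' all samples of all trials, which preserves the x structure and the
#' overall y marginal while destroying the coupling between progression
#' toward the targets and lateral branching — the structure the
#' critical-point fit detects. `"trajectory"` swaps whole y series between
#' trials (resampled by linear interpolation over normalized time when
#' lengths differ); note that on ensembles whose trials share nearly
#' identical x-progressions this scheme approaches the identity and has
#' essentially no power.
#'
#' The statistic (default: the weighted fit quality `r2` of
#' [bifurcation_amplitude()]) is recomputed on each permuted ensemble and
#' `p = (1 + #\{stat_perm \ge stat_obs\}) / (1 + n_perm)`.
#'
#' @param trajectories list of >= 2 trajectory data frames (columns `time`,
#'   `x`, `y`).
#' @param n_perm number of permutations (>= 19).
#' @param statistic function mapping a trajectory list to a scalar;
#'   default: fit quality from [bifurcation_amplitude()] with
#'   `map_args`/`fit_args`. Pass
#'   `function(trs) bifurcation_amplitude(trs)$A` for the raw amplitude.
#' @param scheme `"pointwise"` or `"trajectory"` (see Description).
#' @param map_args,fit_args passed to the default statistic.
#' @param seed RNG seed or `NULL`.
#' @return list with `p`, `observed`, `permuted` (numeric vector).
#' @export
randomization_test <- function(trajectories, n_perm = 99L,
                               statistic = NULL,
                               scheme = c("pointwise", "trajectory"),
                               map_args = list(), fit_args = list(),
                               seed = NULL) {
  stopifnot(length(trajectories) >= 2, n_perm >= 19)
  scheme <- match.arg(scheme)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(statistic))
    statistic <- function(trs)
      bifurcation_amplitude(trs, map_args, fit_args)$r2
  observed <- statistic(trajectories)
  n <- length(trajectories)
  lens <- vapply(trajectories, nrow, integer(1))
  y_pool <- unlist(lapply(trajectories, `[[`, "y"))
  permuted <- vapply(seq_len(n_perm), function(b) {
    swapped <- if (scheme == "pointwise") {
      y_new <- split(y_pool[sample.int(length(y_pool))],
                     rep(seq_len(n), lens))
      lapply(seq_len(n), function(i) {
        tr <- trajectories[[i]]
        tr$y <- y_new[[i]]
        tr
      })
    } else {
      donor <- sample.int(n)
      lapply(seq_len(n), function(i)
        swap_y(trajectories[[i]], trajectories[[donor[i]]]))
    }
    statistic(swapped)
  }, numeric(1))
  list(p = (1 + sum(permuted >= observed)) / (1 + n_perm),
       observed = observed, permuted = permuted)
}

# Replace the y series of `rec` with the y series of `don`, matched on
# normalized time (whole-trajectory y-column swap).
swap_y <- function(rec, don) {
  if (nrow(don) == nrow(rec)) {
    rec$y <- don$y
    return(rec)
  }
  tn_rec <- normalized_time(rec$time)
  tn_don <- normalized_time(don$time)
  rec$y <- approx(tn_don, don$y, xout = tn_rec, rule = 2)$y
  rec
}

normalized_time <- function(tm) {
  rg <- range(tm)
  if (diff(rg) == 0) return(rep(0, length(tm)))
  (tm - rg[1]) / diff(rg)
}
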