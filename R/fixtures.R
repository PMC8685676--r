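#' Deterministic test fixtures
#'
#' Generates the small canned datasets used by the test suite, bitwise
#' reproducible from `seed`: a straight-line track to a target, a
#' synthetic bifurcating ensemble drawn from the branch law
#' `y = +/- A (x - x_c)^alpha` plus Gaussian jitter, and a matching null
#' ensemble whose `y` is a centered random walk with no branch structure.
#'
#' @param seed integer seed.
#' @param n_tracks ensemble size for the bifurcating / null sets.
#' @param x_c,alpha,A branch-law parameters of the bifurcating set.
#' @param noise_sd SD of the y jitter.
#' @return list with elements `straight` (a single trajectory data frame
#'   with `outcome`, `config` and `targets` attributes), `bifurcating` and
#'   `null` (lists of trajectory data frames), and `params`.
#' @export
fixture_generator <- function(seed = 1L, n_tracks = 40L, x_c = 1.0,
                              alpha = 0.5, A = 2.0, noise_sd = 0.05) {
  set.seed(seed)
  x <- seq(0, 4, length.out = 120)

  targets <- target_set(rbind(c(4, 0.5), c(4, -0.5)))
  straight <- data.frame(trial_id = 1L, time = seq_along(x) - 1,
                         x = x, y = x * 0.5 / 4)
  attr(straight, "outcome") <- 1L
  attr(straight, "targets") <- targets
  attr(straight, "config") <- sim_config(
    v0 = sqrt(diff(straight$x[1:2])^2 + diff(straight$y[1:2])^2))

  branch_track <- function(id) {
    side <- if (id %% 2 == 0) 1 else -1
    y <- side * ifelse(x <= x_c, 0, A * (x - x_c)^alpha) +
      rnorm(length(x), 0, noise_sd)
    data.frame(trial_id = id, time = seq_along(x) - 1, x = x, y = y)
  }
  bifurcating <- lapply(seq_len(n_tracks), branch_track)

  null_track <- function(id) {
    y <- cumsum(rnorm(length(x), 0, noise_sd))
    data.frame(trial_id = id, time = seq_along(x) - 1, x = x,
               y = y - mean(y))
  }
  null <- lapply(seq_len(n_tracks), null_track)

  list(straight = straight, bifurcating = bifurcating, null = null,
       params = list(seed = seed, n_tracks = n_tracks, x_c = x_c,
                     alpha = alpha, A = A, noise_sd = noise_sd))
}
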