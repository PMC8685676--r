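#' Target sets: the spatial options offered to the agent
#'
#' A `target_set` holds the positions of the `k` spatial options, plus an
#' optional motion law under which all targets translate in lockstep along a
#' common travel axis, reversing direction at fixed bounds (the
#' "parallel movers" geometry used for social-following scenarios).
#'
#' @param positions numeric matrix with one row per target and columns
#'   `x`, `y` (meters, or the scene's length unit).
#' @param motion `NULL` for static targets, or a list with elements
#'   `axis` (unit 2-vector, direction of travel), `speed` (length/step, > 0)
#'   and `bounds` (length-2 numeric, travel-axis offsets at which the
#'   targets turn around).
#' @param lateral_spacings optional numeric vector of gaps between adjacent
#'   targets perpendicular to the travel axis (recorded for provenance).
#' @return an object of class `target_set` with fields `positions`, `k`,
#'   `motion`, `lateral_spacings`.
#' @examples
#' ts <- target_set(rbind(c(10, 2), c(10, -2)))
#' ts$k
#' @export
target_set <- function(positions, motion = NULL, lateral_spacings = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 2L || nrow(positions) < 1L)
    stop("`positions` must be a k x 2 matrix with k >= 1")
  storage.mode(positions) <- "double"
  colnames(positions) <- c("x", "y")
  if (!is.null(motion)) {
    stopifnot(is.list(motion), length(motion$axis) == 2L,
              motion$speed > 0, length(motion$bounds) == 2L)
    nrm <- sqrt(sum(motion$axis^2))
    if (nrm == 0) stop("motion axis must be nonzero")
    motion$axis <- motion$axis / nrm
    motion$bounds <- sort(as.numeric(motion$bounds))
  }
  structure(list(positions = positions, k = nrow(positions),
                 motion = motion, lateral_spacings = lateral_spacings),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set> k = %d, %s\n", x$k,
              if (is.null(x$motion)) "static"
              else sprintf("moving (speed %.4g along [%.2f, %.2f])",
                           x$motion$speed, x$motion$axis[1], x$motion$axis[2])))
  print(x$positions)
  invisible(x)
}

#' Static multi-target geometries
#'
#' Builds the standard static presets: a symmetric pair (`"two-choice"`),
#' a symmetric pair plus a target on their angle bisector
#' (`"three-choice"`), equidistant/equiangular fans on the same side of the
#' agent (`"fan"`, k in 4:7), or full radial symmetry (`"radial"`).
#' All targets lie at distance `distance` from the origin (the agent's
#' conventional start).
#'
#' @param preset one of `"two-choice"`, `"three-choice"`, `"fan"`, `"radial"`.
#' @param distance radial distance from the origin to every target (> 0).
#' @param angular_span full angle (radians) subtended at the origin between
#'   the two outermost targets (ignored for `"radial"`).
#' @param k number of targets; implied by the named presets
#'   (`two-choice` = 2, `three-choice` = 3), required for `fan`/`radial`.
#' @return a [target_set()].
#' @examples
#' make_static_geometry("three-choice", distance = 10,
#'                      angular_span = 30 * pi / 180)
#' @export
make_static_geometry <- function(preset = c("two-choice", "three-choice",
                                            "fan", "radial"),
                                 distance = 10,
                                 angular_span = 30 * pi / 180,
                                 k = NULL) {
  preset <- match.arg(preset)
  stopifnot(distance > 0)
  bearings <- switch(preset,
    "two-choice" = c(-1, 1) * angular_span / 2,
    "three-choice" = c(-angular_span / 2, 0, angular_span / 2),
    "fan" = {
      if (is.null(k)) stop("`k` required for the fan preset")
      if (k < 2 || k > 7) stop("fan preset supports k in 2..7")
      seq(-angular_span / 2, angular_span / 2, length.out = k)
    },
    "radial" = {
      if (is.null(k)) stop("`k` required for the radial preset")
      if (k < 2 || k > 7) stop("radial preset supports k in 2..7")
      seq(0, 2 * pi, length.out = k + 1)[seq_len(k)]
    })
  pos <- cbind(distance * cos(bearings), distance * sin(bearings))
  target_set(pos)
}

#' Parallel moving-target geometries
#'
#' Builds `k = length(spacings) + 1` targets that travel back and forth in
#' lockstep along `travel_axis`, holding fixed lateral gaps `spacings`
#' between adjacent targets (the virtual-conspecific geometry: two movers a
#' lateral distance L apart, or three movers with gaps `c(L12, L23)`).
#' Targets are centered laterally so the two outermost movers straddle the
#' axis symmetrically, and start at travel-axis offset 0.
#'
#' @param spacings positive numeric vector of adjacent lateral gaps
#'   (length-1 for two movers, length-2 for three, ...). A single mover is
#'   requested with `spacings = numeric(0)` and `k = 1`.
#' @param speed common travel speed (length/step, > 0).
#' @param travel_axis unit 2-vector of travel (default x-axis).
#' @param bounds travel-axis offsets at which the group turns around.
#' @param start_offset lateral position assigned to the first target before
#'   centering; leave default to center the group on the travel axis.
#' @param k number of targets, only needed for the degenerate single-mover
#'   case.
#' @return a [target_set()] with a motion law.
#' @examples
#' make_moving_geometry(c(0.09, 0.03), speed = 0.005)
#' @export
make_moving_geometry <- function(spacings, speed,
                                 travel_axis = c(1, 0),
                                 bounds = c(-0.5, 0.5),
                                 start_offset = 0, k = NULL) {
  spacings <- as.numeric(spacings)
  if (length(spacings) == 0L) {
    if (is.null(k) || k != 1L) stop("empty `spacings` implies k = 1")
    lat <- 0
  } else {
    if (any(spacings <= 0)) stop("spacings must be positive")
    lat <- c(0, -cumsum(spacings))          # first target highest
    lat <- lat - (min(lat) + max(lat)) / 2  # center outermost pair on axis
    lat <- lat + start_offset
  }
  stopifnot(speed > 0)
  axis <- travel_axis / sqrt(sum(travel_axis^2))
  perp <- c(-axis[2], axis[1])
  pos <- outer(lat, perp)  # lateral placement; travel-axis offset 0
  target_set(pos, motion = list(axis = axis, speed = speed, bounds = bounds),
             lateral_spacings = spacings)
}

#' Spin allocation over perceptual clusters of moving targets
#'
#' Parallel movers whose lateral gap is much smaller than the widest gap
#' in the scene act, from the follower's typical vantage well behind the
#' group, as a single perceived option. This helper assigns spins equally
#' across such clusters (and equally within each cluster): adjacent movers
#' are merged when their gap is at most `ratio` times the largest gap.
#' With equal gaps (or two movers) nothing is merged and the allocation
#' reduces to the plain equal split.
#'
#' @param targets a moving [target_set()] built by
#'   [make_moving_geometry()].
#' @param n_spins total number of spins to allocate.
#' @param ratio gap ratio below which adjacent movers merge into one
#'   cluster.
#' @return integer vector of per-target spin counts (a valid `allocation`
#'   for [sim_config()]).
#' @export
cluster_allocation <- function(targets, n_spins, ratio = 0.5) {
  stopifnot(inherits(targets, "target_set"))
  gaps <- targets$lateral_spacings
  k <- targets$k
  if (is.null(gaps) || length(gaps) == 0L || length(unique(gaps)) == 1L) {
    if (n_spins %% k != 0) stop("n_spins must be divisible by k")
    return(rep(n_spins %/% k, k))
  }
  merge <- gaps <= ratio * max(gaps)
  cluster <- cumsum(c(1L, as.integer(!merge)))  # per-target cluster id
  n_cl <- max(cluster)
  sizes <- tabulate(cluster, n_cl)
  if (n_spins %% n_cl != 0 || any((n_spins %/% n_cl) %% sizes != 0))
    stop("n_spins not divisible equally across clusters and members")
  per_cluster <- n_spins %/% n_cl
  as.integer(per_cluster %/% sizes[cluster])
}

#' Target positions at a given lockstep offset
#'
#' @param targets a [target_set()].
#' @param offset travel-axis offset (0 = initial positions).
#' @return k x 2 matrix of positions.
#' @export
target_positions <- function(targets, offset = 0) {
  stopifnot(inherits(targets, "target_set"))
  if (is.null(targets$motion) || offset == 0) return(targets$positions)
  sweep(targets$positions, 2, targets$motion$axis * offset, "+")
}
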