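# Package-wide default temperature for the embodied simulations. The
# hysteresis protocol (estimate_Tc; see the methods vignette) puts the
# disappearance of the bistable region near T_c ~ 0.35 for nu = 0.7,
# N = 60; simulations default to a temperature below that, where the
# decision regime is robust and symmetry breaking is persistent.
DEFAULT_T <- 0.25

# Temperature for the moving-target (social-following) scenes; set so that
# the follower escapes a once-adopted consensus position on the session
# timescale and samples the alternatives, as real followers do.
MOVING_T <- 0.25

#' Scenario presets
#'
#' Named, fully resolvable scenario bundles: target geometry plus the
#' simulation-configuration overrides and the qualitative signature the
#' scenario is expected to show. Static scenes use dimensionless units
#' (targets at distance 10, `v0 = 0.1` per step); moving scenes use meters
#' with the lateral spacings of the social-following experiments.
#'
#' @param name one of `"two-choice"`, `"three-choice"`, `"ring"`,
#'   `"moving-pair"`, `"moving-asymmetric"`.
#' @param ... overrides forwarded to [sim_config()].
#' @return list of class `scenario_preset` with elements `name`, `targets`
#'   (a [target_set()]), `config` (a [sim_config()]), `signature`.
#' @export
scenario_preset <- function(name = c("two-choice", "three-choice", "ring",
                                     "moving-pair", "moving-asymmetric"),
                            ...) {
  name <- match.arg(name)
  static_cfg <- function(..., .base = list()) {
    defaults <- modifyList(list(n_spins = 60L, nu = 0.7, T = DEFAULT_T,
                                sigma_e = 0.3, v0 = 0.1,
                                stop_radius = 0.25, max_steps = 1000L),
                           .base)
    do.call(sim_config, modifyList(defaults, list(...)))
  }
  # fish-like following scenes: meter scale, no capture, follower starts
  # behind the movers; target speed well below v0 so the follower can
  # re-engage after every turn-around and revisit both consensus
  # positions within a session (see the vignette)
  moving_base <- list(nu = 0.7, T = MOVING_T, sigma_e = 0.3, v0 = 0.01,
                      stop_radius = 0, max_steps = 4000L,
                      start = c(-0.15, 0))
  p <- switch(name,
    "two-choice" = list(
      targets = make_static_geometry("two-choice", distance = 10,
                                     angular_span = 30 * pi / 180),
      config = static_cfg(...),
      signature = "1 bifurcation"),
    "three-choice" = list(
      # wider span + sharper tuning than the two-choice scene: decided
      # states must already be stable at mid-range distances for the first
      # elimination to lock in before the central target is reached
      targets = make_static_geometry("three-choice", distance = 10,
                                     angular_span = 60 * pi / 180),
      config = static_cfg(..., .base = list(nu = 0.4)),
      signature = "2 sequential bifurcations"),
    "ring" = list(
      targets = make_static_geometry("radial", distance = 10, k = 6L),
      config = static_cfg(...),
      signature = "repeated bifurcations"),
    "moving-pair" = {
      tg <- make_moving_geometry(0.06, speed = 0.003, bounds = c(-0.5, 0.5))
      list(targets = tg,
           config = static_cfg(..., .base = c(moving_base, list(
             allocation = cluster_allocation(tg, 60L)))),
           signature = "unimodal-to-bimodal with L")
    },
    "moving-asymmetric" = {
      tg <- make_moving_geometry(c(0.09, 0.03), speed = 0.003,
                                 bounds = c(-0.5, 0.5))
      list(targets = tg,
           config = static_cfg(..., .base = c(moving_base, list(
             allocation = cluster_allocation(tg, 60L)))),
           signature = "bimodal lateral modes")
    })
  structure(c(list(name = name), p), class = "scenario_preset")
}

#' Materialize a scenario configuration document
#'
#' Reads a JSON scenario document with sections `targets`, `network`,
#' `noise`, `run` (any of which may be omitted to accept the preset
#' defaults) and returns the resolved preset. The resolved configuration
#' is what every output bundle records for provenance.
#'
#' @param path JSON file path.
#' @return a `scenario_preset`.
#' @export
read_scenario_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  preset <- doc$targets$preset %||% "two-choice"
  p <- scenario_preset(preset)
  if (!is.null(doc$targets$distance) || !is.null(doc$targets$angular_span) ||
      !is.null(doc$targets$k)) {
    kind <- if (preset %in% c("two-choice", "three-choice")) preset
            else "radial"
    p$targets <- make_static_geometry(
      kind,
      distance = doc$targets$distance %||% 10,
      angular_span = (doc$targets$angular_span %||% 30) * pi / 180,
      k = doc$targets$k)
  }
  if (!is.null(doc$targets$spacings))
    p$targets <- make_moving_geometry(
      doc$targets$spacings,
      speed = doc$targets$speed %||% 0.005,
      bounds = doc$targets$bounds %||% c(-0.5, 0.5))
  cfg <- as.list(p$config)
  for (sec in c("network", "noise", "run"))
    for (nm in names(doc[[sec]])) cfg[[nm]] <- doc[[sec]][[nm]]
  p$config <- do.call(sim_config, cfg[setdiff(names(cfg), character(0))])
  p
}

#' Resolved configuration of a preset, for provenance sidecars
#'
#' @param preset a `scenario_preset`.
#' @return plain list safe to serialize as JSON.
#' @export
resolved_config <- function(preset) {
  list(name = preset$name, signature = preset$signature,
       targets = list(positions = preset$targets$positions,
                      k = preset$targets$k,
                      motion = preset$targets$motion,
                      lateral_spacings = preset$targets$lateral_spacings),
       config = unclass(preset$config))
}
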