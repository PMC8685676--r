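#' End-to-end figure-style recipes
#'
#' A recipe runs a full pipeline (simulate, analyze, fit, test) for one
#' scenario and writes an artifact bundle: trajectory CSV (+ JSON
#' sidecar), density-map CSV, fit/summary JSON with the resolved
#' configuration and seed. Recipes are deterministic given `(name, seed)`.
#'
#' Available recipes:
#' \describe{
#'   \item{`two-choice`}{replicate embodied trajectories, folded density
#'     map, piecewise fit and y-swap randomization test.}
#'   \item{`three-choice`}{as above plus the sequential-bifurcation
#'     summary.}
#'   \item{`collective-two-choice`}{zonal-model replicates with omega
#'     feedback; same density/fit/test pipeline on the non-split centroid
#'     trajectories.}
#'   \item{`moving-asymmetric`}{follower behind three asymmetric parallel
#'     movers; lateral-position histogram and mode locations.}
#' }
#'
#' @param name recipe name.
#' @param seed integer seed.
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param n_reps replicate count override (`NULL` = recipe default).
#' @param n_perm permutations for the randomization test.
#' @return the summary list, invisibly when writing files.
#' @export
run_recipe <- function(name, seed = 1L, out_dir = NULL, n_reps = NULL,
                       n_perm = 99L) {
  known <- c("two-choice", "three-choice", "collective-two-choice",
             "moving-asymmetric")
  if (!name %in% known)
    stop("unknown recipe '", name, "'; available: ",
         paste(known, collapse = ", "))
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  summary <- switch(name,
    "two-choice" = ,
    "three-choice" = {
      preset <- scenario_preset(name)
      reps <- n_reps %||% 200L
      ens <- simulate_replicates(reps, preset$targets, preset$config,
                                 base_seed = seed)
      trs <- lapply(ens, as.data.frame)
      amp <- bifurcation_amplitude(trs)
      rt <- randomization_test(trs, n_perm = n_perm, seed = seed + 10^6)
      out <- list(recipe = name, seed = seed, n_reps = reps,
                  outcome_table = as.list(table(attr(ens, "outcomes"))),
                  fit = amp$fit[c("x_c", "alpha", "A", "rss")],
                  p_value = rt$p)
      if (name == "three-choice") {
        sb <- sequential_bifurcation(ens)
        out$sequential <- sb[c("first_outer_fraction", "branch_x",
                               "n_used")]
      }
      if (!is.null(out_dir)) {
        write_trajectories(ens, file.path(out_dir, "trajectories.csv"))
        write_density_csv(amp$map, file.path(out_dir, "density.csv"))
      }
      c(out, list(config = resolved_config(preset)))
    },
    "collective-two-choice" = {
      targets <- make_static_geometry("two-choice", distance = 40,
                                      angular_span = 30 * pi / 180)
      cfg <- collective_config(n_informed_per_target = c(5L, 5L),
                               feedback = TRUE)
      reps <- n_reps %||% 100L
      ens <- simulate_group_replicates(reps, targets, cfg,
                                       base_seed = seed)
      trs <- centroid_trajectories(ens)
      # restrict the analysis window to the approach scene so overshoot
      # excursions past the targets do not stretch the grid
      ma <- list(xlim = c(0, 39), ylim = c(0, 12))
      amp <- bifurcation_amplitude(trs, map_args = ma)
      rt <- randomization_test(trs, n_perm = n_perm, seed = seed + 10^6,
                               map_args = ma)
      if (!is.null(out_dir)) {
        write.csv(do.call(rbind, trs),
                  file.path(out_dir, "centroids.csv"), row.names = FALSE)
        write_density_csv(amp$map, file.path(out_dir, "density.csv"))
      }
      list(recipe = name, seed = seed, n_reps = reps,
           outcome_table = as.list(table(attr(ens, "outcomes"))),
           fit = amp$fit[c("x_c", "alpha", "A", "rss")], p_value = rt$p,
           config = unclass(cfg)[setdiff(names(cfg), "seed")])
    },
    "moving-asymmetric" = {
      preset <- scenario_preset("moving-asymmetric")
      reps <- n_reps %||% 6L
      ens <- simulate_replicates(reps, preset$targets, preset$config,
                                 base_seed = seed, record_targets = TRUE)
      lat <- unlist(lapply(ens, lateral_offsets))
      modes <- lateral_modes(lat, binwidth = 0.005)
      if (!is.null(out_dir))
        write.csv(data.frame(lateral = lat),
                  file.path(out_dir, "lateral_offsets.csv"),
                  row.names = FALSE)
      list(recipe = name, seed = seed, n_reps = reps,
           modes = modes$modes, half_separation = modes$half_separation,
           n_offsets = length(lat), config = resolved_config(preset))
    })

  if (!is.null(out_dir)) {
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", force = TRUE)
    return(invisible(summary))
  }
  summary
}

#' Write a density map as long-format CSV
#'
#' @param map a [density_map()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_density_csv <- function(map, file) {
  pts <- map_points(map)
  write.csv(pts, file, row.names = FALSE)
  invisible(file)
}
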