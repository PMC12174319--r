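# Paradigm orchestration: experiment configuration, single-trial runs,
# sweeps over layouts / motion conditions / speeds, tau1 calibration and
# aggregation utilities.

#' Experiment configuration
#'
#' Bundles the model and paradigm settings. The `"full"` preset uses the
#' model's 86-dva heading-grid extent; the `"desk"` preset restricts the
#' grid to the central 70 dva (the FOV), which leaves the activity map
#' covering every paradigm object position while cutting candidate count,
#' and is the scale used by the package's own validation runs.
#'
#' @param preset `"desk"` or `"full"`.
#' @param grid_extent,grid_spacing heading-grid geometry, dva.
#' @param tau1 flow-parsing threshold.
#' @param tau2_factor detection threshold as a multiple of `tau1`.
#' @param noise_sigma directional-noise standard deviation, degrees.
#' @param hemifield `"none"`, `"same"` or `"opposite"`.
#' @param scenarios scenarios (dot/heading re-randomizations) per layout.
#' @param seed experiment seed; all sub-seeds derive from it.
#' @return an `experiment_config` list.
#' @export
experiment_config <- function(preset = c("desk", "full"),
                              grid_extent = NULL, grid_spacing = 1,
                              tau1 = 3, tau2_factor = 1.5,
                              noise_sigma = 0,
                              hemifield = c("none", "same", "opposite"),
                              scenarios = 5L, seed = 1L) {
  preset <- match.arg(preset)
  hemifield <- match.arg(hemifield)
  if (is.null(grid_extent))
    grid_extent <- if (preset == "full") 86 else 70
  structure(list(preset = preset, grid_extent = grid_extent,
                 grid_spacing = grid_spacing, tau1 = tau1,
                 tau2_factor = tau2_factor, noise_sigma = noise_sigma,
                 hemifield = hemifield, scenarios = as.integer(scenarios),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run the model on one scene and compute all per-trial metrics
#'
#' Applies the configured flow variations (directional noise, hemifield
#' removal) to the scene's combined flow, runs [flow_parse()], and scores
#' the result against the scene's ground truth.
#'
#' @param scene a [build_scene()] result.
#' @param config an [experiment_config()].
#' @param grid optional precomputed [build_heading_grid()].
#' @param noise_seed seed for the directional-noise draw.
#' @return one-row data frame of metrics (see [run_experiment()]).
#' @export
run_trial <- function(scene, config = experiment_config(), grid = NULL,
                      noise_seed = NULL) {
  if (is.null(grid))
    grid <- build_heading_grid(config$grid_extent, config$grid_spacing)
  has_object <- !is.na(scene$lambda)
  flow <- scene$combined
  if (config$hemifield != "none") {
    if (!has_object) stop("hemifield removal requires an object in the scene")
    flow <- remove_hemifield(flow, config$hemifield, scene$offset_direction)
  }
  if (config$noise_sigma > 0)
    flow <- apply_directional_noise(flow, config$noise_sigma, noise_seed)

  obj_dir <- if (has_object) true_combined_direction(scene) else NA_real_
  res <- flow_parse(flow, grid, tau1 = config$tau1,
                    tau2 = config$tau2_factor * config$tau1,
                    reference = if (has_object && !is.na(obj_dir)) obj_dir
                      else NULL)
  offset <- if (has_object) scene$object_center - scene$heading else NULL
  hm <- heading_metrics(scene$heading, res$heading, obj_dir, offset)
  om <- if (has_object) object_metrics(scene, res) else
    list(localization_error = NA_real_, relative_tilt = NA_real_)
  fdm <- if (has_object) flow_deviation_metrics(scene$observer, scene$combined)
    else list(speed_ratio = NA_real_, direction_deviation = NA_real_)

  data.frame(
    lambda = scene$lambda,
    condition = if (has_object) motion_condition(scene$lambda) else "rigid",
    H = scene$H, radius = scene$radius,
    eccentricity = scene$eccentricity,
    offset_direction = scene$offset_direction,
    heading_x = scene$heading[1], heading_y = scene$heading[2],
    est_heading_x = res$heading[1], est_heading_y = res$heading[2],
    n_surfaces = nrow(res$parsing),
    n_object_assigned = sum(res$parsing$assignment == "object"),
    parsing_quality = flow_parsing_quality(res$parsing),
    heading_error = hm$error,
    bias_direction = hm$bias_direction,
    bias_location = hm$bias_location,
    heading_fallback = res$heading_fallback,
    detected = res$detected,
    localization_error = om$localization_error,
    relative_tilt = om$relative_tilt,
    object_direction_est = if (is.null(res$object_direction)) NA_real_
      else res$object_direction,
    combined_direction = obj_dir,
    speed_ratio = fdm$speed_ratio,
    direction_deviation = fdm$direction_deviation)
}

#' Run a paradigm sweep
#'
#' For every layout, `config$scenarios` self-motion scenarios are created
#' (each re-randomizing dots and heading from a sub-seed derived from the
#' experiment seed); each scenario is simulated under every requested
#' motion condition and horizontal speed, sharing the scenario's dots and
#' heading, and the model is run on each flow field. The full paradigm is
#' 147 layouts x 5 scenarios x 45 flow fields.
#'
#' @param config an [experiment_config()].
#' @param layouts data frame of layouts (default [scene_layouts()]), or
#'   `NULL` for object-free scenes.
#' @param lambdas motion conditions to simulate.
#' @param speeds horizontal object speeds, m/s.
#' @return data frame with one row per flow field: provenance columns
#'   (`layout`, `scenario`, `seed`, condition, speed) plus the metrics of
#'   [run_trial()].
#' @export
run_experiment <- function(config = experiment_config(),
                           layouts = scene_layouts(),
                           lambdas = paradigm_constants()$lambda_set,
                           speeds = paradigm_constants()$speed_set) {
  grid <- build_heading_grid(config$grid_extent, config$grid_spacing)
  object_free <- is.null(layouts)
  n_lay <- if (object_free) 1L else nrow(layouts)
  seeds <- matrix(derive_seeds(config$seed, n_lay * config$scenarios),
                  nrow = n_lay)
  rows <- list()
  for (li in seq_len(n_lay)) {
    layout <- if (object_free) NULL else layouts[li, ]
    for (sc in seq_len(config$scenarios)) {
      sseed <- seeds[li, sc]
      conds <- if (object_free) data.frame(lambda = NA, H = NA) else
        expand.grid(H = speeds, lambda = lambdas)
      for (ci in seq_len(nrow(conds))) {
        row <- tryCatch({
          scene <- if (object_free)
            build_scene(NULL, seed = sseed)
          else if (config$hemifield != "none")
            build_scene(layout, conds$lambda[ci], conds$H[ci],
                        heading = c(0, 0), seed = sseed)
          else
            build_scene(layout, conds$lambda[ci], conds$H[ci], seed = sseed)
          tr <- run_trial(scene, config, grid,
                          noise_seed = (sseed + ci) %% .Machine$integer.max)
          cbind(layout = li, scenario = sc, seed = sseed, tr)
        }, error = function(e) {
          warning(sprintf("flow field (layout %d, scenario %d, cond %d) failed: %s",
                          li, sc, ci, conditionMessage(e)))
          NULL
        })
        if (!is.null(row)) rows[[length(rows) + 1L]] <- row
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collect activity-map maxima from object-free scenes
#'
#' Generates `n_scenes` rigid (object-free) paradigm scenes and returns the
#' activity-map maximum of every residual surface, the raw material for
#' calibrating the flow-parsing threshold.
#'
#' @param n_scenes number of scenes.
#' @param config an [experiment_config()].
#' @return numeric vector of activity maxima (about 36 per scene).
#' @export
rigid_surface_maxima <- function(n_scenes = 20, config = experiment_config()) {
  grid <- build_heading_grid(config$grid_extent, config$grid_spacing)
  seeds <- derive_seeds(config$seed, n_scenes)
  unlist(lapply(seeds, function(s) {
    scene <- build_scene(NULL, seed = s)
    res <- flow_parse(scene$combined, grid, tau1 = config$tau1)
    res$parsing$activity_max
  }))
}

#' Calibrate the flow-parsing threshold tau1
#'
#' Sweeps `tau1` over a grid (0 to 4 by 0.25) and returns the smallest
#' value for which at least `target` percent of the rigid-scene surfaces
#' fall at or below threshold (i.e. are routed to the heading layer). With
#' an unreachable target the grid maximum is returned with a warning.
#'
#' @param maxima activity-map maxima from object-free scenes (see
#'   [rigid_surface_maxima()]).
#' @param target target heading-layer rate, percent.
#' @param grid sweep grid for `tau1`.
#' @return the calibrated `tau1`.
#' @export
calibrate_tau1 <- function(maxima, target = 90,
                           grid = seq(0, 4, by = 0.25)) {
  rates <- vapply(grid, function(t) 100 * mean(maxima <= t), numeric(1))
  ok <- which(rates >= target)
  if (length(ok) == 0L) {
    warning("target heading-layer rate unreachable on the tau1 grid")
    return(grid[length(grid)])
  }
  grid[ok[1]]
}

#' Aggregate sweep results by motion condition and speed
#'
#' @param results a [run_experiment()] table.
#' @param by grouping columns.
#' @return data frame of group means: parsing quality, heading error and
#'   biases, detection rate (percent), localization error and tilt.
#' @export
aggregate_results <- function(results, by = c("condition", "H")) {
  num <- c("parsing_quality", "heading_error", "bias_direction",
           "bias_location", "localization_error", "relative_tilt",
           "speed_ratio", "direction_deviation")
  groups <- results[by]
  agg <- aggregate(results[num], by = groups,
                   FUN = function(x) mean(x, na.rm = TRUE))
  det <- aggregate(list(detection_rate = 100 * results$detected),
                   by = groups, FUN = mean)
  n <- aggregate(list(n = rep(1L, nrow(results))), by = groups, FUN = sum)
  out <- merge(merge(agg, det, by = by), n, by = by)
  out[do.call(order, unname(out[by])), ]
}

#' Fig.-style summaries over speed-ratio / direction-deviation bins
#'
#' Bins trials by the flow-deviation metrics (speed-ratio bins of 0.1,
#' deviation bins of 2 degrees) and also extracts the two near-pure slices:
#' trials whose combined flow deviates only in speed (direction deviation
#' at most 1 degree) and only in direction (speed ratio within 10% of 1).
#'
#' @param results a [run_experiment()] table with object trials.
#' @param ratio_bin,deviation_bin bin widths.
#' @return list with `binned` (2D bins), `pure_speed` and
#'   `pure_direction` running summaries.
#' @export
deviation_summary <- function(results, ratio_bin = 0.1, deviation_bin = 2) {
  res <- results[!is.na(results$speed_ratio), , drop = FALSE]
  res$ratio_bin <- ratio_bin * floor(res$speed_ratio / ratio_bin)
  res$dev_bin <- deviation_bin * floor(res$direction_deviation / deviation_bin)
  binned <- aggregate_results(res, by = c("ratio_bin", "dev_bin"))
  pure_speed <- aggregate_results(
    res[res$direction_deviation <= 1, , drop = FALSE], by = "ratio_bin")
  pure_direction <- aggregate_results(
    res[abs(res$speed_ratio - 1) <= 0.1, , drop = FALSE], by = "dev_bin")
  list(binned = binned, pure_speed = pure_speed,
       pure_direction = pure_direction)
}

#' Relative tilt re-expressed toward the heading direction
#'
#' For vertical object placements in the receding condition the tilt
#' pattern is symmetric: objects above the heading tilt downward, objects
#' below tilt upward. This helper re-signs the tilt as positive-toward-FOE
#' for placements above (`offset_direction` 90) and below (270), so
#' symmetric placements can be averaged; lateral placements return `NA`.
#'
#' @param results a [run_experiment()] table.
#' @return numeric vector of toward-FOE tilts, degrees.
#' @export
tilt_toward_foe <- function(results) {
  dirn <- results$offset_direction %% 360
  ifelse(dirn == 90, -results$relative_tilt,
         ifelse(dirn == 270, results$relative_tilt, NA_real_))
}
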