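# Heading estimation from the heading set and object detection /
# localization / direction estimation from the object set.

# Sum surfaces (log-depth values) over the shared candidate grid.
sum_surfaces <- function(surfaces) {
  grid <- surfaces[[1]]$grid
  vals <- Reduce(`+`, lapply(surfaces, surface_values))
  structure(list(grid = grid, loglik = vals,
                 likelihood = if (max(vals) > 0) vals / max(vals) else vals,
                 raw = Reduce(`+`, lapply(surfaces, `[[`, "raw")),
                 id = NA, center = NULL,
                 n_surfaces = length(surfaces)),
            class = "residual_surface")
}

# argmax with deterministic tie-breaking: smallest distance to the FOV
# center, then lexicographic (x, then y).
argmax_candidate <- function(positions, values) {
  mx <- max(values)
  cand <- which(values >= mx - 1e-12 * max(abs(mx), 1))
  if (length(cand) > 1L) {
    d2 <- positions[cand, 1]^2 + positions[cand, 2]^2
    cand <- cand[order(d2, positions[cand, 1], positions[cand, 2])]
  }
  cand[1]
}

#' Estimate heading from the heading-set surfaces
#'
#' Sums the likelihood surfaces assigned to the heading layer into the
#' heading map; the candidate at the map's peak is the heading estimate.
#' With an empty heading set, all surfaces are summed instead and the
#' result is flagged as a fallback. An optional switch uses the argmin of
#' summed raw residuals instead of the argmax of summed likelihoods.
#'
#' @param heading_set list of [residual_surface()]s routed to the heading
#'   layer; may be empty if `all_surfaces` is supplied.
#' @param all_surfaces full surface list, used as fallback when
#'   `heading_set` is empty.
#' @param use_raw if `TRUE`, minimize summed raw residuals instead.
#' @return list with `estimate` (image position, dva), `map` (the summed
#'   surface), and `fallback` flag.
#' @export
estimate_heading <- function(heading_set, all_surfaces = NULL,
                             use_raw = FALSE) {
  fallback <- length(heading_set) == 0L
  if (fallback) {
    if (is.null(all_surfaces) || length(all_surfaces) == 0L)
      stop("no surfaces available for heading estimation")
    heading_set <- all_surfaces
  }
  hm <- sum_surfaces(heading_set)
  score <- if (use_raw) -hm$raw else hm$loglik
  i <- argmax_candidate(hm$grid$positions, score)
  list(estimate = hm$grid$positions[i, ], map = hm, fallback = fallback)
}

#' Detect an independently moving object from the object-set surfaces
#'
#' Sums the surfaces routed to the object layer, computes the saddle-point
#' activity map of the sum, and reports a detection when its maximum
#' exceeds `tau2` (model default `1.5 * tau1 = 4.5`). An empty object set
#' is never a detection.
#'
#' @param object_set list of [residual_surface()]s routed to the object
#'   layer.
#' @param tau2 detection threshold, `> 0`.
#' @param ... passed to [activity_map()] (operator sizes/orientations).
#' @return list with `detected`, `map` (the [activity_map()], `NULL` when
#'   the object set is empty) and `surface` (the summed surface).
#' @export
detect_object <- function(object_set, tau2 = 4.5, ...) {
  stopifnot(tau2 > 0)
  if (length(object_set) == 0L)
    return(list(detected = FALSE, map = NULL, surface = NULL))
  os <- sum_surfaces(object_set)
  amap <- activity_map(os, ...)
  list(detected = amap$max > tau2, map = amap, surface = os)
}

#' Localize the detected object
#'
#' The activity-map location with maximum cumulative activity is the
#' estimated retinal object position. Ties are broken by the highest
#' single-operator activity at the tied locations, then lexicographically.
#'
#' @param detection result of [detect_object()] with `detected = TRUE`.
#' @return image position (dva) of the estimated object location.
#' @export
localize_object <- function(detection) {
  if (!isTRUE(detection$detected)) stop("no detected object to localize")
  amap <- detection$map
  mx <- amap$max
  cand <- which(amap$activity >= mx - 1e-12 * max(mx, 1))
  if (length(cand) > 1L) {
    best1 <- vapply(cand, function(i)
      max(saddle_contributors(detection$surface, amap$locations[i, ],
                              amap$radii, amap$thetas,
                              amap$surround_factor)$activity), numeric(1))
    cand <- cand[order(-best1, amap$locations[cand, 1],
                       amap$locations[cand, 2])]
  }
  amap$locations[cand[1], ]
}

#' Estimate the object's movement direction
#'
#' Every saddle operator contributing nonzero activity at the estimated
#' location offers two opposite peakward directions; the one closer to the
#' reference combined-flow direction is selected (so the estimate never
#' deviates from the reference by more than 90 degrees) and the selected
#' directions are combined by an activity-weighted circular mean.
#'
#' @param detection result of [detect_object()] with `detected = TRUE`.
#' @param location estimated object location (from [localize_object()]).
#' @param reference_direction reference combined-flow direction, degrees.
#' @return list with `direction` (degrees, `NA` when no operator is
#'   active) and `n_operators`.
#' @export
estimate_object_direction <- function(detection, location,
                                      reference_direction) {
  ops <- saddle_contributors(detection$surface, location,
                             detection$map$radii, detection$map$thetas,
                             detection$map$surround_factor)
  ops <- ops[ops$activity > 0, , drop = FALSE]
  if (nrow(ops) == 0L)
    return(list(direction = NA_real_, n_operators = 0L))
  pick <- ifelse(abs(wrap_angle(ops$peak1 - reference_direction)) <=
                   abs(wrap_angle(ops$peak2 - reference_direction)),
                 ops$peak1, ops$peak2)
  list(direction = circular_mean(pick, w = ops$activity),
       n_operators = nrow(ops))
}

#' Reference combined-flow direction near a retinal location
#'
#' The model has no ground-truth access to the object's flow; the reference
#' direction used to disambiguate peakward directions is the circular mean
#' direction of the layer-1 vectors within `radius` of the location.
#'
#' @param rep a [layer1_average()] representation.
#' @param location image position (dva).
#' @param radius neighborhood radius, dva.
#' @return direction in degrees (`NA` if no vectors are in range).
#' @export
reference_direction <- function(rep, location, radius = 5) {
  d2 <- (rep$x - location[1])^2 + (rep$y - location[2])^2
  idx <- which(d2 <= radius^2 & rep$speed > 0)
  if (length(idx) == 0L) return(NA_real_)
  circular_mean(rep$direction[idx])
}
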