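# Performance metrics: flow-parsing quality, heading error and bias
# projections, object detection / localization error / relative tilt.

#' Flow-parsing quality
#'
#' Percentage of residual surfaces whose assignment agrees with their
#' ground-truth causal-source label.
#'
#' @param parsing a [parse_surfaces()] result with a `truth` column.
#' @return percent correct, in `[0, 100]`.
#' @export
flow_parsing_quality <- function(parsing) {
  if (is.null(parsing$truth)) stop("parsing result carries no ground-truth labels")
  100 * mean(parsing$assignment == parsing$truth)
}

#' Heading error and bias projections
#'
#' The heading error is the Euclidean distance (dva) between true and
#' estimated heading. The error vector `estimate - truth` is additionally
#' projected onto the unit object-movement direction (the combined-flow
#' direction) and onto the unit offset vector (object center minus true
#' heading), giving the signed bias along the object's movement and toward
#' its location. The bias toward the location is undefined (`NA`) when the
#' object sits on the heading (zero offset).
#'
#' @param true_heading,estimate image positions, dva.
#' @param object_direction object movement direction in degrees (combined
#'   flow direction), or `NA` for object-free scenes.
#' @param offset object center minus true heading (length-2), or `NULL`.
#' @return list with `error`, `bias_direction`, `bias_location` (dva).
#' @export
heading_metrics <- function(true_heading, estimate, object_direction = NA,
                            offset = NULL) {
  err_vec <- c(estimate[1] - true_heading[1], estimate[2] - true_heading[2])
  error <- sqrt(sum(err_vec^2))
  bias_dir <- if (is.na(object_direction)) NA_real_ else
    sum(err_vec * c(cos(deg2rad(object_direction)),
                    sin(deg2rad(object_direction))))
  bias_loc <- NA_real_
  if (!is.null(offset)) {
    nrm <- sqrt(sum(offset^2))
    if (nrm > 1e-12) bias_loc <- sum(err_vec * offset) / nrm
  }
  list(error = error, bias_direction = bias_dir, bias_location = bias_loc)
}

#' True combined-flow direction of a scene's object
#'
#' Circular mean direction of the combined flow over the object's samples;
#' the ground-truth reference for the relative-tilt metric.
#'
#' @param scene a [build_scene()] result with an object.
#' @return direction in degrees.
#' @export
true_combined_direction <- function(scene) {
  idx <- which(scene$combined$source == "combined")
  if (length(idx) == 0L) stop("scene contains no object")
  sp <- sqrt(scene$combined$vx[idx]^2 + scene$combined$vy[idx]^2)
  ok <- sp > 0
  if (!any(ok)) return(NA_real_)
  circular_mean(rad2deg(atan2(scene$combined$vy[idx][ok],
                              scene$combined$vx[idx][ok])))
}

#' Object localization error and relative tilt
#'
#' Localization error is the distance (dva) between the estimated location
#' and the object's true center. The relative tilt is the signed angle from
#' the true combined-flow direction to the estimated object direction,
#' positive counter-clockwise; following the evaluation convention it is
#' only computed when the object was detected and localized within
#' `tilt_radius` (10 dva) of its center.
#'
#' @param scene a [build_scene()] result with an object.
#' @param result a [flow_parse_result][flow_parse()].
#' @param tilt_radius localization radius (dva) gating the tilt.
#' @return list with `localization_error` and `relative_tilt` (degrees,
#'   `NA` when not detected / not localized / direction undefined).
#' @export
object_metrics <- function(scene, result, tilt_radius = 10) {
  if (!isTRUE(result$detected))
    return(list(localization_error = NA_real_, relative_tilt = NA_real_))
  loc_err <- sqrt(sum((result$object_location - scene$object_center)^2))
  tilt <- NA_real_
  if (loc_err <= tilt_radius && !is.na(result$object_direction)) {
    true_dir <- true_combined_direction(scene)
    if (!is.na(true_dir))
      tilt <- wrap_angle(result$object_direction - true_dir)
  }
  list(localization_error = loc_err, relative_tilt = tilt)
}
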