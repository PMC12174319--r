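# End-to-end model: flow field in, estimates out.

#' Run the full model on one flow field
#'
#' Pipeline: layer-1 vector averaging, layer-2 receptive-field grouping and
#' residual surfaces, layer-3 activity maps, flow parsing at `tau1`, heading
#' estimation from the heading set, and object detection (`tau2`),
#' localization and direction estimation from the object set.
#'
#' @param flow a [flow_field()] (the combined flow presented to the model).
#' @param grid a [build_heading_grid()]; its extent bounds both the heading
#'   space and the residual-surface domain.
#' @param tau1 flow-parsing activity threshold (default 3).
#' @param tau2 detection threshold (default `1.5 * tau1`).
#' @param truth optional logical vector of ground-truth contains-object
#'   labels per group (see [ground_truth_source()]); computed from the flow
#'   field's source tags when `NULL`.
#' @param min_group_size minimum flow vectors per residual surface.
#' @param use_raw_heading use argmin of raw residuals for the heading map.
#' @param reference reference combined-flow direction (degrees) used to
#'   disambiguate peakward directions in the object-direction estimate.
#'   `NULL` (default) derives it from the model's own layer-1 vectors near
#'   the estimated location ([reference_direction()]); evaluation runs pass
#'   the scene's true combined-flow direction instead, since a local flow
#'   average mixes background motion into the reference.
#' @param ... passed to [activity_map()].
#' @return a `flow_parse_result`: list with `heading` (estimate, dva),
#'   `heading_fallback`, `detected`, `object_location`, `object_direction`,
#'   `reference_direction`, `parsing` (per-surface [parse_surfaces()]
#'   table), `surfaces`, `n_vectors`, and the thresholds used.
#' @export
flow_parse <- function(flow, grid = build_heading_grid(), tau1 = 3,
                       tau2 = 1.5 * tau1, truth = NULL,
                       min_group_size = 10L, use_raw_heading = FALSE,
                       reference = NULL, ...) {
  rep <- layer1_average(flow)
  groups <- layer2_group(rep)
  sizes <- vapply(groups, function(g) length(g$members), integer(1))
  kept <- which(sizes >= min_group_size)
  if (length(kept) == 0L) stop("no layer-2 group reaches the minimum size")
  if (length(kept) < length(groups))
    message(sprintf("dropped %d layer-2 group(s) below %d vectors",
                    length(groups) - length(kept), min_group_size))
  surfaces <- lapply(groups[kept], function(g)
    residual_surface(rep[g$members, ], grid, min_size = min_group_size,
                     id = g$id, center = g$center))
  if (is.null(truth)) truth <- ground_truth_source(groups)
  maps <- activity_map(surfaces, ...)
  parsing <- parse_surfaces(surfaces, tau1, maps = maps,
                            truth = truth[kept])

  heading_set <- surfaces[parsing$assignment == "heading"]
  hd <- estimate_heading(heading_set, all_surfaces = surfaces,
                         use_raw = use_raw_heading)

  object_set <- surfaces[parsing$assignment == "object"]
  det <- detect_object(object_set, tau2, ...)
  loc <- NULL; dir <- NA_real_; refd <- NA_real_
  if (det$detected) {
    loc <- localize_object(det)
    refd <- if (is.null(reference)) reference_direction(rep, loc) else reference
    if (!is.na(refd))
      dir <- estimate_object_direction(det, loc, refd)$direction
  }

  structure(list(heading = hd$estimate, heading_fallback = hd$fallback,
                 detected = det$detected, object_location = loc,
                 object_direction = dir, reference_direction = refd,
                 parsing = parsing, surfaces = surfaces,
                 detection = det, n_vectors = nrow(rep),
                 tau1 = tau1, tau2 = tau2),
            class = "flow_parse_result")
}

#' @export
print.flow_parse_result <- function(x, ...) {
  cat(sprintf("<flow_parse_result> heading (%.2f, %.2f) dva%s\n",
              x$heading[1], x$heading[2],
              if (x$heading_fallback) " [fallback: empty heading set]" else ""))
  cat(sprintf("  %d surfaces: %d heading, %d object (tau1 = %g)\n",
              nrow(x$parsing), sum(x$parsing$assignment == "heading"),
              sum(x$parsing$assignment == "object"), x$tau1))
  if (x$detected)
    cat(sprintf("  object detected at (%g, %g), direction %.1f deg (tau2 = %g)\n",
                x$object_location[1], x$object_location[2],
                x$object_direction, x$tau2))
  else cat(sprintf("  no object detected (tau2 = %g)\n", x$tau2))
  invisible(x)
}
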