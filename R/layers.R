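# Model layers 1-3.
#
# Layer 1 averages the raw flow into a vector representation on a regular
# operator grid (circular receptive fields, radius 2 dva). Layer 2 groups
# those vectors into overlapping 20-dva receptive fields (36 groups on the
# 70-dva FOV) and computes one residual surface per group. Layer 3 runs
# multi-scale saddle-point operators over each (likelihood-transformed)
# surface and sums them into an activity map whose maximum drives the flow
# parsing decision at threshold tau1.

#' Layer-1 operator grid
#'
#' Operators sit on a rectangular grid with spacing 4/3 dva, shifted by
#' (1/3, 1/3) dva so that no operator center coincides with a heading
#' candidate of the hexagonal grid (candidates too close to flow-vector
#' positions destabilize the residual computation). The spacing calibrates
#' the full 70-dva field to roughly 2760 output vectors.
#'
#' @param fov field-of-view width, dva.
#' @param spacing operator spacing, dva.
#' @param offset grid shift, dva.
#' @return matrix of operator centers (x, y).
#' @export
layer1_grid <- function(fov = 70, spacing = 4 / 3, offset = c(1 / 3, 1 / 3)) {
  n <- floor(fov / spacing) + 1
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  centers <- cbind(x = rep(ax + offset[1], times = n),
                   y = rep(ax + offset[2], each = n))
  centers
}

#' Layer 1: vector representation of the flow
#'
#' Each operator averages the flow samples within its circular receptive
#' field: arithmetic mean of speeds and circular mean of directions,
#' recomposed into one vector. Empty receptive fields produce no vector.
#' The number of object (`"combined"`) samples entering each average is
#' recorded for ground-truth evaluation.
#'
#' @param flow a [flow_field()].
#' @param centers operator centers (default [layer1_grid()]).
#' @param rf_radius receptive-field radius, dva.
#' @return a `vector_rep` data frame: `x`, `y` (operator center), `vx`,
#'   `vy`, `speed`, `direction`, `n`, `n_object`.
#' @export
layer1_average <- function(flow, centers = layer1_grid(), rf_radius = 2) {
  if (nrow(flow) == 0L) stop("flow field is empty")
  sp <- attr(centers, "spacing")
  # assign samples to nearby operators via the regular grid structure
  xs <- sort(unique(centers[, 1]))
  ys <- sort(unique(centers[, 2]))
  step <- xs[2] - xs[1]
  nx <- length(xs); ny <- length(ys)
  ix_lo <- pmax(1L, ceiling((flow$x - rf_radius - xs[1]) / step) + 1L)
  ix_hi <- pmin(nx, floor((flow$x + rf_radius - xs[1]) / step) + 1L)
  iy_lo <- pmax(1L, ceiling((flow$y - rf_radius - ys[1]) / step) + 1L)
  iy_hi <- pmin(ny, floor((flow$y + rf_radius - ys[1]) / step) + 1L)
  nxw <- pmax(0L, ix_hi - ix_lo + 1L)
  nyw <- pmax(0L, iy_hi - iy_lo + 1L)
  reps <- nxw * nyw
  keep <- reps > 0L
  si <- rep(which(keep), reps[keep])
  ix <- unlist(lapply(which(keep), function(i)
    rep(ix_lo[i]:ix_hi[i], times = nyw[i])), use.names = FALSE)
  iy <- unlist(lapply(which(keep), function(i)
    rep(iy_lo[i]:iy_hi[i], each = nxw[i])), use.names = FALSE)
  ox <- xs[ix]; oy <- ys[iy]
  inside <- (flow$x[si] - ox)^2 + (flow$y[si] - oy)^2 <= rf_radius^2
  si <- si[inside]; op <- (iy[inside] - 1L) * nx + ix[inside]
  if (length(si) == 0L) stop("no samples fall inside any receptive field")
  speed <- sqrt(flow$vx[si]^2 + flow$vy[si]^2)
  dirx <- ifelse(speed > 0, flow$vx[si] / speed, 0)
  diry <- ifelse(speed > 0, flow$vy[si] / speed, 0)
  is_obj <- as.integer(flow$source[si] == "combined")
  agg <- rowsum(cbind(speed, dirx, diry, 1, is_obj), group = op)
  ops <- as.integer(rownames(agg))
  n <- agg[, 4]
  mean_speed <- agg[, 1] / n
  ang <- atan2(agg[, 3], agg[, 2])
  res_len <- sqrt(agg[, 2]^2 + agg[, 3]^2)
  # degenerate circular mean (perfectly opposing directions): zero vector
  mean_speed[res_len < 1e-12] <- 0
  out <- data.frame(x = xs[(ops - 1L) %% nx + 1L],
                    y = ys[(ops - 1L) %/% nx + 1L],
                    vx = mean_speed * cos(ang), vy = mean_speed * sin(ang),
                    speed = mean_speed, direction = rad2deg(ang),
                    n = n, n_object = agg[, 5])
  out <- out[order(out$y, out$x), ]
  rownames(out) <- NULL
  class(out) <- c("vector_rep", "data.frame")
  out
}

#' Layer-2 receptive-field centers
#'
#' @param fov field-of-view width, dva.
#' @param spacing center spacing, dva (default 12).
#' @return matrix of group centers; 36 (6 x 6) for the 70-dva FOV.
#' @export
layer2_centers <- function(fov = 70, spacing = 12) {
  n <- max(1L, round(fov / spacing))
  ax <- (seq_len(n) - (n + 1) / 2) * spacing
  cbind(x = rep(ax, times = n), y = rep(ax, each = n))
}

#' Layer 2: group layer-1 vectors into overlapping receptive fields
#'
#' Receptive fields have radius 20 dva on centers 12 dva apart; a vector may
#' belong to several groups.
#'
#' @param rep a [layer1_average()] output.
#' @param centers group centers (default [layer2_centers()]).
#' @param rf_radius receptive-field radius, dva.
#' @return list of groups, each with `id`, `center`, `members` (row indices
#'   into `rep`), `contains_object` (ground-truth label: at least one member
#'   vector averaged over an object sample).
#' @export
layer2_group <- function(rep, centers = layer2_centers(), rf_radius = 20) {
  lapply(seq_len(nrow(centers)), function(g) {
    d2 <- (rep$x - centers[g, 1])^2 + (rep$y - centers[g, 2])^2
    members <- which(d2 <= rf_radius^2)
    list(id = g, center = centers[g, ], members = members,
         contains_object = any(rep$n_object[members] > 0))
  })
}

#' Activity of one saddle-point operator (reference implementation)
#'
#' The operator's receptive field is five equal circular areas in a cross:
#' a central disc of radius `r` at `position` plus four surround discs at
#' distance `surround_factor * r` along the orientation axis and its
#' perpendicular. The surface value is averaged within each disc (mean over
#' the surface's candidates falling inside); with `d_i` the four
#' surround-minus-center differences in angular order, activity is
#' `sum(|d_i|)` if the signs alternate strictly around the cross and zero
#' otherwise. The peakward directions are the two opposite directions toward
#' the higher-valued surrounds.
#'
#' @param surface a [residual_surface()] (its `loglik` values are used, or
#'   `likelihood` when absent), or a list with `grid` and one of those
#'   fields.
#' @param position operator location (x, y) in dva.
#' @param r disc radius, dva.
#' @param theta orientation of the cross, degrees.
#' @param surround_factor surround distance in units of `r` (default 2:
#'   surrounds tangent to the central disc).
#' @return list with `activity` (0 if inactive) and `peakward` (two
#'   directions in degrees, or `NULL` when inactive).
#' @export
saddle_activity <- function(surface, position, r, theta,
                            surround_factor = 2) {
  pos <- surface$grid$positions
  vals <- surface_values(surface)
  half <- surface$grid$extent / 2
  disc <- function(q) {
    if (q[1] - r < -half || q[1] + r > half ||
        q[2] - r < -half || q[2] + r > half) return(NA_real_)
    inside <- (pos[, 1] - q[1])^2 + (pos[, 2] - q[2])^2 <= r^2
    if (!any(inside)) return(NA_real_)
    mean(vals[inside])
  }
  ctr <- disc(position)
  angs <- theta + c(0, 90, 180, 270)
  sur <- vapply(angs, function(a)
    disc(position + surround_factor * r * unit_deg(a)), numeric(1))
  if (is.na(ctr) || anyNA(sur)) return(list(activity = 0, peakward = NULL))
  d <- sur - ctr
  alt <- (d[1] > 0 && d[3] > 0 && d[2] < 0 && d[4] < 0) ||
         (d[1] < 0 && d[3] < 0 && d[2] > 0 && d[4] > 0)
  if (!alt) return(list(activity = 0, peakward = NULL))
  pk <- if (d[1] > 0) theta + c(0, 180) else theta + c(90, 270)
  list(activity = sum(abs(d)), peakward = pk %% 360)
}

#' All saddle operators of the layer-3 group at one location
#'
#' Evaluates the full multi-scale group (all sizes times orientations, 30
#' operators by default) at a single surface location.
#'
#' @inheritParams saddle_activity
#' @param radii disc radii, dva.
#' @param thetas orientations, degrees.
#' @return data frame with `r`, `theta`, `activity`, `peak1`, `peak2`
#'   (peakward directions, `NA` when inactive).
#' @export
saddle_contributors <- function(surface, position, radii = 1:5,
                                thetas = seq(0, 75, by = 15),
                                surround_factor = 2) {
  grid <- expand.grid(r = radii, theta = thetas)
  acts <- lapply(seq_len(nrow(grid)), function(i)
    saddle_activity(surface, position, grid$r[i], grid$theta[i],
                    surround_factor))
  data.frame(r = grid$r, theta = grid$theta,
             activity = vapply(acts, `[[`, numeric(1), "activity"),
             peak1 = vapply(acts, function(a)
               if (is.null(a$peakward)) NA_real_ else a$peakward[1], numeric(1)),
             peak2 = vapply(acts, function(a)
               if (is.null(a$peakward)) NA_real_ else a$peakward[2], numeric(1)))
}

# Surface values read by the saddle operators and the heading map: the
# log-depth surface when present, else the normalized likelihood.
surface_values <- function(s) {
  if (!is.null(s$loglik)) s$loglik else s$likelihood
}

# Activity-map grid: 1-dva locations leaving a border margin so the largest
# operator's five areas fit inside the surface extent.
activity_map_locations <- function(extent, radii = 1:5, surround_factor = 2) {
  margin <- (surround_factor + 1) * max(radii)
  k <- floor(extent / 2 - margin)
  if (k < 0) stop("surface extent too small for the operator group")
  ax <- seq(-k, k)
  cbind(x = rep(ax, times = length(ax)), y = rep(ax, each = length(ax)))
}

#' Layer 3: saddle-operator activity map(s)
#'
#' At every location of a 1-dva grid over the surface, the multi-scale
#' operator group (5 sizes x 6 orientations by default) is evaluated on the
#' likelihood surface and the member activities are summed into a cumulative
#' activity. The grid is restricted so that all five areas of the largest
#' operator fit inside the surface extent.
#'
#' @param surfaces a single [residual_surface()] or a list of surfaces
#'   sharing one heading grid.
#' @param radii disc radii, dva.
#' @param thetas orientations, degrees.
#' @param surround_factor surround distance in units of `r`.
#' @return for a single surface an `activity_map` (list with `locations`,
#'   `activity`, `max`, `argmax`); for a list, a list of activity maps.
#' @export
activity_map <- function(surfaces, radii = 1:5, thetas = seq(0, 75, by = 15),
                         surround_factor = 2) {
  single <- inherits(surfaces, "residual_surface")
  if (single) surfaces <- list(surfaces)
  grid <- surfaces[[1]]$grid
  vals <- vapply(surfaces, surface_values, numeric(nrow(grid$positions)))
  vals <- matrix(vals, nrow = nrow(grid$positions))
  locs <- activity_map_locations(grid$extent, radii, surround_factor)
  act <- activity_maps_cpp(grid$positions, vals, locs, radii, thetas,
                           surround_factor, grid$extent)
  maps <- lapply(seq_along(surfaces), function(k) {
    a <- act[, k]
    structure(list(locations = locs, activity = a, max = max(a),
                   argmax = locs[which.max(a), ],
                   radii = radii, thetas = thetas,
                   surround_factor = surround_factor),
              class = "activity_map")
  })
  if (single) maps[[1]] else maps
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> %d locations, max %.3f at (%g, %g)\n",
              nrow(x$locations), x$max, x$argmax[1], x$argmax[2]))
  invisible(x)
}

#' Write an activity map as tab-delimited text
#'
#' @param map an [activity_map()].
#' @param path file path.
#' @export
write_activity_map <- function(map, path) {
  df <- data.frame(x = map$locations[, 1], y = map$locations[, 2],
                   activity = map$activity)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flow parsing: route residual surfaces by activity-map maximum
#'
#' Surfaces whose activity-map maximum does not exceed `tau1` are assigned
#' to the heading-estimation layer; the rest to the object-estimation layer.
#'
#' @param surfaces list of [residual_surface()]s.
#' @param tau1 activity threshold (model default 3).
#' @param maps optional precomputed [activity_map()]s (list parallel to
#'   `surfaces`).
#' @param truth optional logical vector: ground-truth contains-object label
#'   per surface (for evaluation).
#' @return a `parsing_result` data frame: `id`, `activity_max`,
#'   `assignment` (`"heading"`/`"object"`), and `truth` label when given.
#' @export
parse_surfaces <- function(surfaces, tau1 = 3, maps = NULL, truth = NULL) {
  stopifnot(tau1 >= 0)
  if (is.null(maps)) maps <- activity_map(surfaces)
  amax <- vapply(maps, `[[`, numeric(1), "max")
  out <- data.frame(
    id = vapply(surfaces, function(s) as.integer(s$id), integer(1)),
    activity_max = amax,
    assignment = ifelse(amax > tau1, "object", "heading"))
  if (!is.null(truth))
    out$truth <- ifelse(truth, "object", "heading")
  class(out) <- c("parsing_result", "data.frame")
  out
}

#' Ground-truth causal source of a layer-2 group
#'
#' A group is labeled as containing the object if at least one of its
#' layer-1 member vectors averaged over one or more object samples. Used for
#' evaluation only; the model itself has no access to these labels.
#'
#' @param groups output of [layer2_group()].
#' @return logical vector, `TRUE` where the group contains object flow.
#' @export
ground_truth_source <- function(groups) {
  vapply(groups, `[[`, logical(1), "contains_object")
}
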