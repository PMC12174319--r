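# Instantaneous optic flow on a planar pinhole image.
#
# The image plane sits at the focal constant f in front of the observer, image
# coordinates are in dva (see flow_focal()) with +x to the observer's right
# and +y upward. A scene point P = (X, Y, Z) in meters projects to
# p = f * (X/Z, Y/Z); its image velocity under instantaneous observer
# translation T (m/s) and rotation Omega (rad/s) is
#   v(p) = (1/Z) A(p) T + B(p) Omega.

#' Project a 3D scene point onto the image plane
#'
#' @param P numeric of length 3 `(X, Y, Z)` in meters, or an `n x 3` matrix.
#'   `Z` must be positive (in front of the observer).
#' @param f focal constant (default [flow_focal()]).
#' @return image position(s) in dva: length-2 vector or `n x 2` matrix.
#' @export
project_point <- function(P, f = flow_focal()) {
  P <- if (is.matrix(P)) P else matrix(P, ncol = 3)
  if (any(P[, 3] <= 0)) stop("point behind observer: Z must be > 0")
  out <- f * cbind(P[, 1] / P[, 3], P[, 2] / P[, 3])
  colnames(out) <- c("x", "y")
  if (nrow(out) == 1L) drop(out) else out
}

# Translation Jacobian A(p), 2 x 3. Flow from translation T is (1/Z) A(p) T.
A_matrix <- function(p, f = flow_focal()) {
  rbind(c(-f, 0, p[1]),
        c(0, -f, p[2]))
}

# Rotation Jacobian B(p), 2 x 3. Flow from rotation Omega is B(p) Omega,
# independent of depth.
B_matrix <- function(p, f = flow_focal()) {
  x <- p[1]; y <- p[2]
  rbind(c(x * y / f, -f - x^2 / f, y),
        c(f + y^2 / f, -x * y / f, -x))
}

#' Image velocity of a static scene point
#'
#' Evaluates `v(p) = (1/Z) A(p) T + B(p) Omega` for one or many samples.
#'
#' @param p image position(s) in dva, length-2 vector or `n x 2` matrix.
#' @param Z depth(s) in meters, positive.
#' @param T_obs observer translation, m/s, length 3.
#' @param Omega observer rotation, rad/s, length 3 (default zero).
#' @param f focal constant.
#' @return image velocity in dva/s, same shape as `p`.
#' @export
flow_vector <- function(p, Z, T_obs, Omega = c(0, 0, 0), f = flow_focal()) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  if (any(Z <= 0)) stop("invalid depth: Z must be > 0")
  x <- p[, 1]; y <- p[, 2]
  vx <- (-f * T_obs[1] + x * T_obs[3]) / Z +
    (x * y / f) * Omega[1] + (-f - x^2 / f) * Omega[2] + y * Omega[3]
  vy <- (-f * T_obs[2] + y * T_obs[3]) / Z +
    (f + y^2 / f) * Omega[1] + (-x * y / f) * Omega[2] - x * Omega[3]
  out <- cbind(vx = vx, vy = vy)
  if (nrow(out) == 1L) drop(out) else out
}

#' Image velocity contributed by independent object motion
#'
#' An object point moving with world velocity `S` adds
#' `v_O(p) = (1/Z) A(p) (-S)` to the observer flow; the combined flow at the
#' sample is `v(p) + v_O(p)`.
#'
#' @inheritParams flow_vector
#' @param S object world velocity, m/s, length 3.
#' @return image velocity component in dva/s due to the object's own motion.
#' @export
object_flow <- function(p, Z, S, f = flow_focal()) {
  flow_vector(p, Z, -S, f = f)
}

#' Construct a flow field
#'
#' A flow field is a data frame of image samples: position (`x`, `y` in dva),
#' velocity (`vx`, `vy` in dva/s) and a `source` tag recording the causal
#' source of each sample's motion: `"observer"` for static background dots,
#' `"combined"` for dots on the independently moving object.
#'
#' @param x,y,vx,vy numeric vectors of equal length.
#' @param source character vector, `"observer"` or `"combined"`.
#' @param Z optional depths (m) retained for bookkeeping.
#' @return a `flow_field` (data frame).
#' @export
flow_field <- function(x, y, vx, vy, source = "observer", Z = NULL) {
  source <- rep_len(as.character(source), length(x))
  stopifnot(all(source %in% c("observer", "combined")))
  df <- data.frame(x = x, y = y, vx = vx, vy = vy, source = source)
  if (!is.null(Z)) df$Z <- Z
  class(df) <- c("flow_field", "data.frame")
  df
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> %d samples (%d observer, %d combined)\n",
              nrow(x), sum(x$source == "observer"),
              sum(x$source == "combined")))
  NextMethod()
}

#' Rotate background flow vectors by Gaussian directional noise
#'
#' Each background (`source == "observer"`) vector is rotated by an
#' independent angle drawn from a zero-mean Gaussian with standard deviation
#' `sigma` degrees; magnitudes are untouched. Object (`"combined"`) vectors
#' are left unchanged.
#'
#' @param flow a [flow_field()].
#' @param sigma noise standard deviation in degrees, `>= 0`.
#' @param seed optional integer seed for reproducibility.
#' @return the perturbed flow field.
#' @export
apply_directional_noise <- function(flow, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(flow)
  if (!is.null(seed)) set.seed(seed)
  idx <- which(flow$source == "observer")
  ang <- deg2rad(rnorm(length(idx), 0, sigma))
  ca <- cos(ang); sa <- sin(ang)
  vx <- flow$vx[idx]; vy <- flow$vy[idx]
  flow$vx[idx] <- ca * vx - sa * vy
  flow$vy[idx] <- sa * vx + ca * vy
  flow
}

#' Remove background flow from one hemifield
#'
#' Splits the field of view along the axis through the FOV center
#' perpendicular to the object's offset direction and removes background
#' samples from one half. Object samples are always retained.
#'
#' @param flow a [flow_field()].
#' @param side `"same"` keeps background flow in the object's hemifield,
#'   `"opposite"` keeps only the other half.
#' @param offset_direction direction (degrees, counter-clockwise from
#'   rightward) from the FOV center toward the object.
#' @return the reduced flow field.
#' @export
remove_hemifield <- function(flow, side = c("same", "opposite"),
                             offset_direction) {
  side <- match.arg(side)
  u <- c(cos(deg2rad(offset_direction)), sin(deg2rad(offset_direction)))
  proj <- flow$x * u[1] + flow$y * u[2]
  in_object_half <- proj >= 0
  keep <- flow$source == "combined" |
    (if (side == "same") in_object_half else !in_object_half)
  out <- flow[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Speed-ratio and direction-deviation of combined versus observer flow
#'
#' Quantifies how much the object's motion perturbs the flow at its retinal
#' location: the speed ratio is the mean combined-flow speed divided by the
#' mean observer-flow speed over the object's samples, and the direction
#' deviation is the mean unsigned angle between paired combined and observer
#' vectors.
#'
#' @param observer_flow,combined_flow paired [flow_field()]s over the same
#'   samples (as produced by [build_scene()]).
#' @return list with `speed_ratio` and `direction_deviation` (degrees).
#' @export
flow_deviation_metrics <- function(observer_flow, combined_flow) {
  stopifnot(nrow(observer_flow) == nrow(combined_flow))
  idx <- which(combined_flow$source == "combined")
  if (length(idx) == 0L) stop("no object samples present")
  vo <- cbind(observer_flow$vx[idx], observer_flow$vy[idx])
  vc <- cbind(combined_flow$vx[idx], combined_flow$vy[idx])
  mean_obs <- mean(sqrt(rowSums(vo^2)))
  if (mean_obs == 0) stop("zero observer speed at all object samples")
  list(speed_ratio = mean(sqrt(rowSums(vc^2))) / mean_obs,
       direction_deviation = mean(angle_between(vc, vo)))
}

#' Read or write a flow field as tab-delimited text
#'
#' Files carry the header `x_dva y_dva vx_dva_s vy_dva_s source` with one
#' sample per row.
#'
#' @param flow a [flow_field()].
#' @param path file path.
#' @return `read_flow_field` returns a [flow_field()]; `write_flow_field`
#'   returns `path` invisibly.
#' @export
write_flow_field <- function(flow, path) {
  df <- data.frame(x_dva = flow$x, y_dva = flow$y,
                   vx_dva_s = flow$vx, vy_dva_s = flow$vy,
                   source = flow$source)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_field
#' @export
read_flow_field <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("x_dva", "y_dva", "vx_dva_s", "vy_dva_s", "source")
  if (!all(need %in% names(df)))
    stop("flow-field file must have columns: ", paste(need, collapse = " "))
  flow_field(df$x_dva, df$y_dva, df$vx_dva_s, df$vy_dva_s, df$source)
}
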