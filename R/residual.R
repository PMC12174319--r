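# Subspace algorithm: residual of fitting a flow field with a candidate
# translation direction, minimized over the per-sample depths and the
# rotation. R_v(T) is the squared norm of the projection of the stacked flow
# onto the orthogonal complement of the constraint matrix C(T).

#' Constraint matrix C(T) of the subspace algorithm
#'
#' Builds the dense `2n x (n+3)` matrix whose first `n` columns hold the
#' block-diagonal translation fields `A(p_i) T` and whose last three columns
#' stack the rotation Jacobians `B(p_i)`. Flow consistent with translation
#' direction `T` (any depths, any rotation) lies in its column space.
#'
#' @param T_cand unit 3D translation direction (see
#'   [candidate_translation()]), or an image position of length 2.
#' @param points `n x 2` matrix of image positions (dva), `n >= 3`.
#' @param f focal constant.
#' @return the `2n x (n+3)` constraint matrix.
#' @export
build_C <- function(T_cand, points, f = flow_focal()) {
  if (length(T_cand) == 2L) T_cand <- candidate_translation(T_cand, f)
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("insufficient data: need at least 3 points for a nontrivial complement")
  C <- matrix(0, 2 * n, n + 3)
  for (i in seq_len(n)) {
    rows <- (2 * i - 1):(2 * i)
    C[rows, i] <- A_matrix(points[i, ], f) %*% T_cand
    C[rows, n + (1:3)] <- B_matrix(points[i, ], f)
  }
  C
}

#' Subspace residual of a flow field for one candidate translation
#'
#' Equals the least-squares residual of fitting the stacked flow `v` by the
#' columns of `C(T)`: depth scalings of the candidate's translation field
#' plus an arbitrary rotational field. Computed without forming `C(T)`: each
#' flow vector is projected onto the unit perpendicular of the candidate's
#' radial direction at the sample (removing the depth unknown), then the
#' rank-3 rotational subspace is projected out.
#'
#' @param v stacked flow components `(vx1, vy1, ..., vxn, vyn)`, or an
#'   `n x 2` matrix of velocities.
#' @inheritParams build_C
#' @return the scalar residual `R_v(T) >= 0`.
#' @export
residual <- function(v, T_cand, points, f = flow_focal()) {
  points <- as.matrix(points)
  vel <- if (is.matrix(v)) v else matrix(v, ncol = 2, byrow = TRUE)
  stopifnot(nrow(vel) == nrow(points))
  if (length(T_cand) == 3L) {
    # convert a 3D direction back to its image position for the kernel
    if (T_cand[3] <= 0) stop("candidate translation must have positive Z component")
    T_cand <- f * c(T_cand[1] / T_cand[3], T_cand[2] / T_cand[3])
  }
  drop(residual_surface_cpp(points, vel, matrix(T_cand, ncol = 2), f))
}

#' Residual surface of a flow-vector group over the heading grid
#'
#' Evaluates the subspace residual at every candidate of the grid and
#' transforms the raw values into a heading-likelihood map. The working
#' transform is `loglik = -log(max(raw / max(raw), eps))`: the negative
#' logarithm of the max-scaled residual (floored at `eps` to absorb exact
#' zeros), which is 0 at the raw maximum and grows as the residual valley
#' deepens; this is the surface the saddle-point operators and the heading
#' map read, so that operator activity reflects the depth of surface
#' structure in log units rather than being renormalized away on nearly
#' flat surfaces. `likelihood` is the same surface min-max scaled to
#' `[0, 1]` (1 at the raw minimum, 0 at the raw maximum), convenient for
#' display and comparison across surfaces.
#'
#' @param group data frame (or list) with sample positions `x`, `y` (dva)
#'   and velocities `vx`, `vy` (dva/s), e.g. one layer-2 receptive-field
#'   group of layer-1 vectors.
#' @param grid a [build_heading_grid()].
#' @param f focal constant.
#' @param min_size minimum number of flow vectors (default 10); smaller
#'   groups are rejected.
#' @param eps relative floor applied to raw residuals before the logarithm.
#' @param id,center optional group identifier and receptive-field center.
#' @return a `residual_surface`: list with `grid`, `raw`, `loglik`,
#'   `likelihood`, `id`, `center`, `n_samples`.
#' @export
residual_surface <- function(group, grid, f = flow_focal(), min_size = 10L,
                             eps = 1e-12, id = NA, center = NULL) {
  pts <- cbind(group$x, group$y)
  vel <- cbind(group$vx, group$vy)
  if (nrow(pts) < min_size)
    stop(sprintf("group below minimum size (%d < %d)", nrow(pts), min_size))
  raw <- drop(residual_surface_cpp(pts, vel, grid$positions, f))
  ll <- loglik_transform(raw, eps)
  structure(list(grid = grid, raw = raw, loglik = ll,
                 likelihood = if (max(ll) > 0) ll / max(ll) else ll,
                 id = id, center = center, n_samples = nrow(pts)),
            class = "residual_surface")
}

# Negative log of the max-scaled residual, floored at eps.
loglik_transform <- function(raw, eps = 1e-12) {
  mx <- max(raw)
  if (mx <= 0) return(rep(0, length(raw)))
  -log(pmax(raw / mx, eps))
}

#' @export
print.residual_surface <- function(x, ...) {
  cat(sprintf(
    "<residual_surface> group %s (n=%d), %d candidates, raw min %.3g at (%.1f, %.1f)\n",
    as.character(x$id), x$n_samples, length(x$raw), min(x$raw),
    x$grid$positions[which.min(x$raw), 1], x$grid$positions[which.min(x$raw), 2]))
  invisible(x)
}

#' Write a residual surface as tab-delimited text
#'
#' Columns: candidate `x`, `y` (dva), `raw` residual, `likelihood`.
#'
#' @param surface a [residual_surface()].
#' @param path file path.
#' @export
write_residual_surface <- function(surface, path) {
  df <- data.frame(x = surface$grid$positions[, 1],
                   y = surface$grid$positions[, 2],
                   raw = surface$raw, likelihood = surface$likelihood)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
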