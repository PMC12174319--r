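# Independent oracles used across the test files. These deliberately avoid
# the package's computational paths: projection is differentiated by finite
# differences, the subspace residual is computed from a dense QR of the full
# constraint matrix, and disc averages are taken by polar quadrature.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Finite-difference image velocity: move the 3D point under relative motion
# -T - Omega x P for a tiny dt and difference the projections.
fd_flow_oracle <- function(p, Z, T_obs, Omega = c(0, 0, 0),
                           f = flow_focal(), dt = 1e-7) {
  P <- c(p[1] * Z / f, p[2] * Z / f, Z)
  P2 <- P + dt * (-T_obs - cross3(Omega, P))
  p2 <- f * c(P2[1] / P2[3], P2[2] / P2[3])
  (p2 - p) / dt
}

# Dense-QR residual: squared norm of the projection of v onto the orthogonal
# complement of the column space of C(T).
residual_brute <- function(v, T_cand, points, f = flow_focal()) {
  C <- build_C(T_cand, points, f)
  qrC <- qr(C)
  Q <- qr.Q(qrC)[, seq_len(qrC$rank), drop = FALSE]
  sum(v^2) - sum((crossprod(Q, v))^2)
}

# Noiseless rigid flow group: n random dots, exact flow for heading at image
# position `heading`, no averaging. Returns a residual_surface()-ready frame.
make_rigid_group <- function(n, heading, seed, span = 25, Omega = c(0, 0, 0),
                             f = flow_focal()) {
  set.seed(seed)
  pts <- cbind(x = runif(n, -span, span), y = runif(n, -span, span))
  Z <- runif(n, 4, 10)
  T_obs <- 2 * candidate_translation(heading, f)
  v <- flow_vector(pts, Z, T_obs, Omega, f)
  data.frame(x = pts[, 1], y = pts[, 2], vx = v[, 1], vy = v[, 2],
             Z = Z, T1 = T_obs[1], T2 = T_obs[2], T3 = T_obs[3])
}

# Mean of f over a disc by polar quadrature (midpoint in r^2 and angle).
polar_disc_mean <- function(fun, center, r, nr = 400, na = 256) {
  u <- (seq_len(nr) - 0.5) / nr        # uniform in r^2 for equal-area rings
  rad <- r * sqrt(u)
  ang <- 2 * pi * (seq_len(na) - 0.5) / na
  xs <- center[1] + outer(rad, cos(ang))
  ys <- center[2] + outer(rad, sin(ang))
  mean(fun(xs, ys))
}

# A dense rectangular sampling "grid" standing in for a residual surface, so
# analytic surfaces can be fed to the saddle operators. The default step is
# a power of two so that disc-boundary comparisons stay exact and symmetric.
dense_grid <- function(extent, h = 0.125) {
  ax <- seq(-extent / 2, extent / 2, by = h)
  list(positions = cbind(x = rep(ax, times = length(ax)),
                         y = rep(ax, each = length(ax))),
       extent = extent, spacing = h)
}

analytic_surface <- function(fun, extent, h = 0.125) {
  g <- dense_grid(extent, h)
  list(grid = g, loglik = fun(g$positions[, 1], g$positions[, 2]))
}

# Hex-grid surface from an analytic function.
hex_surface <- function(fun, extent = 40, spacing = 1) {
  g <- build_heading_grid(extent, spacing)
  list(grid = g, loglik = fun(g$positions[, 1], g$positions[, 2]))
}

desk_config <- function(seed = 1L, ...) {
  experiment_config("desk", seed = seed, ...)
}
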