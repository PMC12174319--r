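# Angle helpers (degrees) and circular statistics used across layers.

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

#' Wrap angles into (-180, 180]
#'
#' @param a angles in degrees.
#' @return wrapped angles in degrees.
#' @export
wrap_angle <- function(a) {
  w <- (a + 180) %% 360 - 180
  w[w == -180] <- 180
  w
}

#' Weighted circular mean of directions
#'
#' Directions are treated as unit vectors, summed with the given weights, and
#' the direction of the resultant is returned. The resultant length is zero
#' (and the mean undefined, returned as `NA`) for perfectly opposing input.
#'
#' @param angles directions in degrees.
#' @param w non-negative weights, recycled to `length(angles)`.
#' @return mean direction in degrees in (-180, 180], or `NA` if undefined.
#' @export
circular_mean <- function(angles, w = 1) {
  w <- rep_len(w, length(angles))
  sx <- sum(w * cos(deg2rad(angles)))
  sy <- sum(w * sin(deg2rad(angles)))
  if (sqrt(sx^2 + sy^2) < 1e-12 * max(sum(abs(w)), 1e-300)) return(NA_real_)
  rad2deg(atan2(sy, sx))
}

# Unit vector for a direction in degrees, exact at the cardinal angles so
# that axis-aligned geometry stays symmetric to the last bit.
unit_deg <- function(deg) {
  m <- deg %% 360
  if (m == 0) c(1, 0)
  else if (m == 90) c(0, 1)
  else if (m == 180) c(-1, 0)
  else if (m == 270) c(0, -1)
  else c(cos(deg2rad(deg)), sin(deg2rad(deg)))
}

# Unsigned angle between paired 2D vectors (rows), in degrees.
angle_between <- function(u, v) {
  dot <- rowSums(u * v)
  nu <- sqrt(rowSums(u^2))
  nv <- sqrt(rowSums(v^2))
  cosang <- pmin(1, pmax(-1, dot / (nu * nv)))
  rad2deg(acos(cosang))
}

# Deterministic derivation of sub-seeds from one experiment seed. Keeps all
# derived seeds below 2^31 so they remain valid R integers.
derive_seeds <- function(seed, n) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n, replace = FALSE)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
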