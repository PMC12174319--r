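# Simulation paradigm: observer translation at 2 m/s toward a dot cloud
# (depth 4-10 m, 0.55 dots/dva^2 over a 70 x 70 dva window) containing one
# opaque, circular, independently moving object of 50 dots. Object world
# motion is H + lambda * T: a horizontal component to the observer's right
# plus a depth component tied to the observer translation.

#' Paradigm constants
#'
#' @return a list with the fixed scene parameters of the simulation paradigm:
#'   FOV width (dva), background dot density (dots/dva^2), cloud depth range
#'   (m), observer speed (m/s), object dot count, heading-zone radius (dva),
#'   the lambda set and the horizontal-speed set.
#' @export
paradigm_constants <- function() {
  list(fov = 70, density = 0.55, depth_range = c(4, 10), observer_speed = 2,
       object_dots = 50L, heading_zone_radius = 5,
       lambda_set = c(-1, -0.5, 0, 0.5, 1),
       speed_set = seq(0, 1, by = 0.125))
}

#' Names of the object motion-in-depth conditions
#'
#' @param lambda depth-motion coefficient(s) in `{-1, -0.5, 0, 0.5, 1}`.
#' @return condition names, from `"approaching"` (`-1`) to `"receding"` (`1`).
#' @export
motion_condition <- function(lambda) {
  nm <- c(`-1` = "approaching", `-0.5` = "semi-approaching", `0` = "neutral",
          `0.5` = "semi-receding", `1` = "receding")
  out <- nm[as.character(lambda)]
  if (any(is.na(out))) stop("lambda must be one of -1, -0.5, 0, 0.5, 1")
  unname(out)
}

#' Enumerate the spatial layouts of the paradigm
#'
#' Objects come in three sizes (diameters 1, 4 and 8 dva) and are placed
#' relative to the heading direction at eccentricities 0, 5, 10 and 15 dva in
#' one of 16 directions spaced 22.5 degrees, starting rightward and moving
#' counter-clockwise. Eccentricity 0 collapses all directions onto a single
#' position, giving 49 positions and 147 layouts.
#'
#' @param eccentricities eccentricities in dva (default paradigm set).
#' @param radii object radii in dva (default paradigm sizes).
#' @return data frame with columns `radius`, `eccentricity`, `direction`.
#' @export
scene_layouts <- function(eccentricities = c(0, 5, 10, 15),
                          radii = c(0.5, 2, 4)) {
  rows <- list()
  for (r in radii) {
    for (ecc in eccentricities) {
      dirs <- if (ecc == 0) 0 else seq(0, 337.5, by = 22.5)
      rows[[length(rows) + 1L]] <-
        data.frame(radius = r, eccentricity = ecc, direction = dirs)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build one paradigm scene and its flow fields
#'
#' Background dots are uniform over the viewing window with uniform depths in
#' the cloud range; 50 object dots are uniform over the object's circular
#' image region, at the cloud front (Z = 4 m) in the receding condition
#' (`lambda = 1`) and uniform in depth otherwise. Background dots that
#' project inside the object silhouette and lie behind the object's nearest
#' dot are occluded. The observer translates at 2 m/s toward a heading drawn
#' uniformly from the central 10-dva disc (unless given); the object moves
#' with world velocity `S = (H, 0, 0) + lambda * T`.
#'
#' @param layout one row of [scene_layouts()] (or a list with `radius`,
#'   `eccentricity`, `direction`), or `NULL` for an object-free scene.
#' @param lambda depth-motion coefficient in `{-1, -0.5, 0, 0.5, 1}`.
#' @param H horizontal object speed, m/s (paradigm uses 0 to 1 by 0.125).
#' @param heading image position of the true heading (dva); `NULL` draws it
#'   uniformly from the disc of radius 5 dva about the FOV center.
#' @param seed optional integer seed; identical seeds give identical scenes.
#' @param f focal constant.
#' @return a `flow_scene`: list with paired `observer` and `combined`
#'   [flow_field()]s (row-aligned) and the ground-truth scene parameters
#'   (`heading`, `object_center`, `radius`, `lambda`, `H`, `T_obs`, `S`).
#' @export
build_scene <- function(layout = NULL, lambda = 0, H = 0, heading = NULL,
                        seed = NULL, f = flow_focal()) {
  pc <- paradigm_constants()
  if (!is.null(seed)) set.seed(seed)
  half <- pc$fov / 2

  if (is.null(heading)) {
    r <- pc$heading_zone_radius * sqrt(runif(1))
    a <- runif(1, 0, 2 * pi)
    heading <- c(r * cos(a), r * sin(a))
  }
  T_obs <- c(heading[1] / f, heading[2] / f, 1)
  T_obs <- pc$observer_speed * T_obs / sqrt(sum(T_obs^2))

  n_bg <- round(pc$density * pc$fov^2)
  bg <- data.frame(x = runif(n_bg, -half, half),
                   y = runif(n_bg, -half, half),
                   Z = runif(n_bg, pc$depth_range[1], pc$depth_range[2]))

  has_object <- !is.null(layout)
  if (has_object) {
    stopifnot(lambda %in% pc$lambda_set)
    center <- heading + layout$eccentricity *
      c(cos(deg2rad(layout$direction)), sin(deg2rad(layout$direction)))
    rr <- layout$radius * sqrt(runif(pc$object_dots))
    aa <- runif(pc$object_dots, 0, 2 * pi)
    ob <- data.frame(x = center[1] + rr * cos(aa),
                     y = center[2] + rr * sin(aa))
    ob$Z <- if (lambda == 1) pc$depth_range[1] else
      runif(pc$object_dots, pc$depth_range[1], pc$depth_range[2])
    # opacity: drop background dots projecting into the silhouette behind
    # the object's nearest dot
    d2 <- (bg$x - center[1])^2 + (bg$y - center[2])^2
    occluded <- d2 < layout$radius^2 & bg$Z > min(ob$Z)
    bg <- bg[!occluded, , drop = FALSE]
    if (nrow(bg) == 0L) stop("degenerate configuration: no background dots remain")
    S <- c(H, 0, 0) + lambda * T_obs
  } else {
    center <- NULL
    S <- c(0, 0, 0)
    ob <- NULL
  }

  pts <- rbind(bg, ob)
  src <- rep(c("observer", "combined"), c(nrow(bg), if (has_object) nrow(ob) else 0L))
  v_obs <- flow_vector(as.matrix(pts[, c("x", "y")]), pts$Z, T_obs, f = f)
  observer <- flow_field(pts$x, pts$y, v_obs[, 1], v_obs[, 2], src, Z = pts$Z)
  vc <- v_obs
  if (has_object) {
    oi <- which(src == "combined")
    v_o <- object_flow(as.matrix(pts[oi, c("x", "y")]), pts$Z[oi], S, f = f)
    vc[oi, ] <- vc[oi, ] + v_o
  }
  combined <- flow_field(pts$x, pts$y, vc[, 1], vc[, 2], src, Z = pts$Z)

  structure(list(observer = observer, combined = combined,
                 heading = heading, object_center = center,
                 radius = if (has_object) layout$radius else NA_real_,
                 eccentricity = if (has_object) layout$eccentricity else NA_real_,
                 offset_direction = if (has_object) layout$direction else NA_real_,
                 lambda = if (has_object) lambda else NA_real_,
                 H = if (has_object) H else NA_real_,
                 T_obs = T_obs, S = S, f = f),
            class = "flow_scene")
}

#' @export
print.flow_scene <- function(x, ...) {
  cat(sprintf("<flow_scene> heading (%.2f, %.2f) dva, %d samples",
              x$heading[1], x$heading[2], nrow(x$combined)))
  if (!is.na(x$lambda))
    cat(sprintf("; object r=%g dva at (%.2f, %.2f), %s, H=%g m/s",
                x$radius, x$object_center[1], x$object_center[2],
                motion_condition(x$lambda), x$H))
  cat("\n")
  invisible(x)
}
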