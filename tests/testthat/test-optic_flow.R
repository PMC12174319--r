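test_that("pinhole projection follows f*(X/Z, Y/Z) and rejects points behind the observer", {
  expect_equal(unname(project_point(c(0, 0, 5))), c(0, 0))
  expect_equal(unname(project_point(c(1, 2, 4), f = 1)), c(0.25, 0.5))
  p1 <- project_point(c(1.3, -0.7, 5))
  p2 <- project_point(c(1.3, -0.7, 10))
  expect_equal(unname(p2), unname(p1) / 2)
  expect_error(project_point(c(1, 1, 0)), "behind")
  expect_error(project_point(c(1, 1, -2)), "behind")
})

test_that("flow vectors match a finite-difference projection oracle", {
  expect_equal(unname(flow_vector(c(0, 0), 5, c(0, 0, 2))), c(0, 0))
  # rotation-driven flow is depth independent
  vrot1 <- flow_vector(c(5, -3), 1, c(0, 0, 0), Omega = c(0, 0, 0.1))
  vrot2 <- flow_vector(c(5, -3), 100, c(0, 0, 0), Omega = c(0, 0, 0.1))
  expect_equal(vrot1, vrot2)
  set.seed(4)
  for (i in 1:8) {
    p <- runif(2, -30, 30)
    Z <- runif(1, 2, 12)
    T_obs <- rnorm(3)
    Om <- rnorm(3) * 0.05
    expect_equal(unname(flow_vector(p, Z, T_obs, Om)),
                 fd_flow_oracle(p, Z, T_obs, Om), tolerance = 1e-5)
  }
  expect_error(flow_vector(c(1, 1), -3, c(0, 0, 2)), "depth")
})

test_that("combined object flow is observer flow plus object flow", {
  T_obs <- 2 * candidate_translation(c(2, -1))
  p <- c(8, 5); Z <- 6
  # object moving with the observer's translation plus nothing: S = T cancels
  vc <- flow_vector(p, Z, T_obs) + object_flow(p, Z, T_obs)
  expect_equal(unname(vc), c(0, 0), tolerance = 1e-12)
  # receding condition: combined flow is purely horizontal
  S <- c(0.5, 0, 0) + 1 * T_obs
  vc <- flow_vector(p, Z, T_obs) + object_flow(p, Z, S)
  expect_equal(unname(vc[2]), 0, tolerance = 1e-12)
  expect_gt(vc[1], 0)  # rightward world motion, rightward flow
  # static object: combined equals observer flow
  expect_equal(flow_vector(p, Z, T_obs) + object_flow(p, Z, c(0, 0, 0)),
               flow_vector(p, Z, T_obs))
})

test_that("scene construction obeys density, depth, occlusion and additivity", {
  sc0 <- build_scene(NULL, seed = 5)
  expect_equal(nrow(sc0$combined), round(0.55 * 70 * 70))  # 2695 dots
  expect_true(all(sc0$combined$source == "observer"))
  expect_true(all(abs(sc0$combined$x) <= 35 & abs(sc0$combined$y) <= 35))
  expect_true(all(sc0$combined$Z >= 4 & sc0$combined$Z <= 10))
  # FOE property: flow points radially away from the heading, zero at FOE
  dp <- cbind(sc0$combined$x - sc0$heading[1], sc0$combined$y - sc0$heading[2])
  vv <- cbind(sc0$combined$vx, sc0$combined$vy)
  cosang <- rowSums(dp * vv) / (sqrt(rowSums(dp^2)) * sqrt(rowSums(vv^2)))
  expect_true(all(cosang > 1 - 1e-9))

  lay <- list(radius = 2, eccentricity = 10, direction = 90)
  sc <- build_scene(lay, lambda = -0.5, H = 0.25, seed = 6)
  obj <- sc$combined$source == "combined"
  expect_equal(sum(obj), 50L)
  # occlusion: no background dot behind the object inside its silhouette
  d2 <- (sc$combined$x - sc$object_center[1])^2 +
        (sc$combined$y - sc$object_center[2])^2
  behind <- !obj & d2 < lay$radius^2 & sc$combined$Z > min(sc$combined$Z[obj])
  expect_equal(sum(behind), 0L)
  # additivity at object samples, machine precision
  p <- cbind(sc$combined$x, sc$combined$y)[obj, ]
  vo <- object_flow(p, sc$combined$Z[obj], sc$S)
  expect_equal(cbind(sc$combined$vx, sc$combined$vy)[obj, ],
               unname(cbind(sc$observer$vx, sc$observer$vy)[obj, ] + vo),
               tolerance = 1e-12)
  # receding objects sit at the cloud front
  scr <- build_scene(lay, lambda = 1, H = 0.5, seed = 6)
  expect_true(all(scr$combined$Z[scr$combined$source == "combined"] == 4))
})

test_that("identical seeds reproduce scenes bit-identically across motion conditions", {
  lay <- list(radius = 2, eccentricity = 5, direction = 45)
  a <- build_scene(lay, lambda = 0, H = 0.5, seed = 77)
  b <- build_scene(lay, lambda = 0, H = 0.5, seed = 77)
  expect_identical(a$combined, b$combined)
  expect_identical(a$heading, b$heading)
  # a scenario seed pins dots and heading while lambda and H vary
  c2 <- build_scene(lay, lambda = -1, H = 0.125, seed = 77)
  expect_identical(a$heading, c2$heading)
  expect_identical(a$combined$x, c2$combined$x)
})

test_that("directional noise rotates background vectors only, preserving speed", {
  lay <- list(radius = 2, eccentricity = 5, direction = 0)
  sc <- build_scene(lay, lambda = 0, H = 0.5, seed = 3)
  expect_identical(apply_directional_noise(sc$combined, 0), sc$combined)
  nz <- apply_directional_noise(sc$combined, 15, seed = 9)
  sp0 <- sqrt(sc$combined$vx^2 + sc$combined$vy^2)
  sp1 <- sqrt(nz$vx^2 + nz$vy^2)
  expect_equal(sp1, sp0, tolerance = 1e-12)
  obj <- sc$combined$source == "combined"
  expect_identical(nz$vx[obj], sc$combined$vx[obj])
  bg <- !obj
  expect_true(all(abs(nz$vx[bg] - sc$combined$vx[bg]) > 0 |
                  abs(nz$vy[bg] - sc$combined$vy[bg]) > 0))
  expect_identical(apply_directional_noise(sc$combined, 15, seed = 9), nz)
})

test_that("hemifield removal keeps the object and splits background correctly", {
  lay <- list(radius = 2, eccentricity = 5, direction = 90)
  sc <- build_scene(lay, lambda = 1, H = 0.5, heading = c(0, 0), seed = 8)
  same <- remove_hemifield(sc$combined, "same", 90)
  opp <- remove_hemifield(sc$combined, "opposite", 90)
  expect_true(all(same$y[same$source == "observer"] >= 0))
  expect_true(all(opp$y[opp$source == "observer"] < 0))
  expect_equal(sum(same$source == "combined"), 50L)
  expect_equal(sum(opp$source == "combined"), 50L)
  n_bg <- sum(sc$combined$source == "observer")
  expect_equal(nrow(same) + nrow(opp), n_bg + 100L)
})

test_that("flow deviation metrics recover constructed speed and direction changes", {
  mkpair <- function(vc) {
    obs <- flow_field(1:4, rep(0, 4), rep(1, 4), rep(0, 4), "combined")
    cmb <- flow_field(1:4, rep(0, 4), vc[, 1], vc[, 2], "combined")
    list(obs, cmb)
  }
  # no object motion
  p <- mkpair(cbind(rep(1, 4), rep(0, 4)))
  m <- flow_deviation_metrics(p[[1]], p[[2]])
  expect_equal(m$speed_ratio, 1)
  expect_equal(m$direction_deviation, 0)
  # doubled speed
  m <- flow_deviation_metrics(p[[1]], mkpair(cbind(rep(2, 4), rep(0, 4)))[[2]])
  expect_equal(m$speed_ratio, 2)
  expect_equal(m$direction_deviation, 0)
  # rotated by 30 degrees
  rot <- cbind(rep(cos(pi / 6), 4), rep(sin(pi / 6), 4))
  m <- flow_deviation_metrics(p[[1]], mkpair(rot)[[2]])
  expect_equal(m$speed_ratio, 1, tolerance = 1e-12)
  expect_equal(m$direction_deviation, 30, tolerance = 1e-9)
})

test_that("flow fields and scene configs round-trip through their text formats", {
  lay <- list(radius = 0.5, eccentricity = 15, direction = 225)
  sc <- build_scene(lay, lambda = 0.5, H = 0.375, seed = 21)
  tf <- tempfile(fileext = ".tsv")
  write_flow_field(sc$combined, tf)
  back <- read_flow_field(tf)
  expect_equal(back$x, sc$combined$x)
  expect_equal(back$vx, sc$combined$vx)
  expect_identical(back$source, sc$combined$source)

  cfgf <- tempfile(fileext = ".cfg")
  cfg <- list(radius = 0.5, eccentricity = 15, direction = 225, lambda = 0.5,
              H = 0.375, seed = 21, noise_sigma = 0, hemifield = "none")
  write_scene_config(cfg, cfgf)
  cfg2 <- read_scene_config(cfgf)
  expect_equal(cfg2[names(cfg)], cfg)
  sim <- scene_from_config(cfg2)
  expect_equal(sim$scene$combined$vx, sc$combined$vx)
})
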