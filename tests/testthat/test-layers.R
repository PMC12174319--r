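test_that("layer-1 operators average speed and direction circularly", {
  # uniform flow inside one receptive field reproduces the vector
  fl <- flow_field(x = c(0.2, 0.5, 0.4), y = c(0.3, 0.1, 0.5),
                   vx = rep(1.5, 3), vy = rep(-0.5, 3))
  rep1 <- layer1_average(fl)
  hit <- rep1[rep1$n == 3, ]
  expect_true(all(abs(hit$vx - 1.5) < 1e-12 & abs(hit$vy + 0.5) < 1e-12))
  # two unit vectors at 0 and 90 degrees: speed 1, direction 45
  fl2 <- flow_field(x = c(0.3, 0.4), y = c(0.3, 0.4),
                    vx = c(1, 0), vy = c(0, 1))
  rep2 <- layer1_average(fl2)
  hit2 <- rep2[rep2$n == 2, ][1, ]
  expect_equal(hit2$speed, 1)
  expect_equal(hit2$direction, 45, tolerance = 1e-9)
  expect_equal(hit2$vx, cos(pi / 4), tolerance = 1e-12)
})

test_that("a full-field flow yields about 2760 layer-1 vectors", {
  sc <- build_scene(NULL, seed = 19)
  rep1 <- layer1_average(sc$combined)
  expect_lt(abs(nrow(rep1) - 2760) / 2760, 0.05)
})

test_that("layer-1 vectors record how many object samples they averaged", {
  lay <- list(radius = 4, eccentricity = 5, direction = 180)
  sc <- build_scene(lay, lambda = 0, H = 0.5, seed = 23)
  rep1 <- layer1_average(sc$combined)
  # brute-force recount for a few operators
  idx <- sample(nrow(rep1), 25)
  for (i in idx) {
    d2 <- (sc$combined$x - rep1$x[i])^2 + (sc$combined$y - rep1$y[i])^2
    inside <- d2 <= 4
    expect_equal(rep1$n[i], sum(inside))
    expect_equal(rep1$n_object[i], sum(inside & sc$combined$source == "combined"))
  }
})

test_that("layer-2 grouping makes 36 overlapping receptive fields on the 70-dva FOV", {
  cen <- layer2_centers()
  expect_equal(nrow(cen), 36L)
  expect_equal(sort(unique(cen[, 1])), c(-30, -18, -6, 6, 18, 30))
  # adjacent centers 12 dva apart with radius-20 fields: neighbors overlap
  expect_lt(12, 2 * 20)
  sc <- build_scene(NULL, seed = 29)
  rep1 <- layer1_average(sc$combined)
  groups <- layer2_group(rep1)
  expect_length(groups, 36L)
  # membership equals brute-force distance enumeration
  g <- groups[[14]]
  d2 <- (rep1$x - g$center[1])^2 + (rep1$y - g$center[2])^2
  expect_equal(g$members, which(d2 <= 400))
  # a central vector belongs to every group within 20 dva
  vi <- which.min(rep1$x^2 + rep1$y^2)
  holds <- vapply(groups, function(g) {
    d <- sqrt(sum((c(rep1$x[vi], rep1$y[vi]) - g$center)^2))
    (vi %in% g$members) == (d <= 20)
  }, logical(1))
  expect_true(all(holds))
})

test_that("saddle operator reproduces the closed-form activity on z = x^2 - y^2", {
  d <- 2; r <- 1
  surf <- analytic_surface(function(x, y) x^2 - y^2, extent = 20, h = 0.125)
  res <- saddle_activity(surf, c(0, 0), r = r, theta = 0)
  expect_equal(res$activity, 4 * d^2, tolerance = 1e-6)
  expect_equal(sort(res$peakward), c(0, 180))
  # quadrature oracle for the area means used by the combination rule
  m_c <- polar_disc_mean(function(x, y) x^2 - y^2, c(0, 0), r)
  m_r <- polar_disc_mean(function(x, y) x^2 - y^2, c(d, 0), r)
  m_u <- polar_disc_mean(function(x, y) x^2 - y^2, c(0, d), r)
  expect_equal(m_c, 0, tolerance = 1e-7)
  expect_equal(m_r, d^2, tolerance = 1e-6)
  expect_equal(m_u, -d^2, tolerance = 1e-6)
  expect_equal(abs(m_r - m_c) + abs(m_u - m_c) * 2 + abs(m_r - m_c),
               4 * d^2, tolerance = 1e-5)
})

test_that("saddle operators are silent on constant and radially peaked surfaces", {
  flat <- analytic_surface(function(x, y) rep(0.7, length(x)), extent = 16, h = 0.2)
  peak <- analytic_surface(function(x, y) exp(-(x^2 + y^2) / 18), extent = 16, h = 0.2)
  for (th in seq(0, 75, 15)) {
    expect_equal(saddle_activity(flat, c(0, 0), 1, th)$activity, 0)
    expect_equal(saddle_activity(peak, c(0, 0), 1, th)$activity, 0)
    expect_equal(saddle_activity(peak, c(2, 1), 1.5, th)$activity, 0)
  }
  # an operator whose areas leave the surface is inactive
  expect_equal(saddle_activity(peak, c(7.5, 0), 1, 0)$activity, 0)
})

test_that("saddle activity is shift invariant and scales linearly", {
  surf <- analytic_surface(function(x, y) x^2 - y^2 + 0.1 * x, extent = 20, h = 0.125)
  a0 <- saddle_activity(surf, c(0.5, -0.3), 2, 15)$activity
  surf_shift <- surf; surf_shift$loglik <- surf$loglik + 5
  expect_equal(saddle_activity(surf_shift, c(0.5, -0.3), 2, 15)$activity, a0)
  surf_scaled <- surf; surf_scaled$loglik <- 3 * surf$loglik
  expect_equal(saddle_activity(surf_scaled, c(0.5, -0.3), 2, 15)$activity,
               3 * a0, tolerance = 1e-12)
})

test_that("the multi-scale group has 30 operators and the C++ map matches the R path", {
  surf <- hex_surface(function(x, y)
    exp(-((x - 4)^2 + y^2) / 10) + exp(-((x + 4)^2 + y^2) / 10), extent = 40)
  ops <- saddle_contributors(surf, c(0, 0))
  expect_equal(nrow(ops), 30L)
  expect_equal(nrow(unique(ops[c("r", "theta")])), 30L)
  amap <- activity_map(structure(surf, class = "residual_surface"))
  for (k in sample(nrow(amap$locations), 12)) {
    loc <- amap$locations[k, ]
    ops_k <- saddle_contributors(surf, loc)
    expect_equal(amap$activity[k], sum(ops_k$activity), tolerance = 1e-10)
  }
  # the two-peak surface has its activity maximum at the saddle between them
  expect_lte(sqrt(sum(amap$argmax^2)), 1.5)
})

test_that("flow parsing is monotone in tau1 and routes by activity maxima", {
  grid <- build_heading_grid(40, 1)
  sc <- build_scene(list(radius = 2, eccentricity = 5, direction = 0),
                    lambda = 1, H = 0.75, seed = 41)
  rep1 <- layer1_average(sc$combined)
  groups <- layer2_group(rep1)
  surfaces <- lapply(groups[1:12], function(g)
    residual_surface(rep1[g$members, ], grid, id = g$id, center = g$center))
  maps <- activity_map(surfaces)
  p_inf <- parse_surfaces(surfaces, tau1 = Inf, maps = maps)
  expect_true(all(p_inf$assignment == "heading"))
  p0 <- parse_surfaces(surfaces, tau1 = 0, maps = maps)
  expect_identical(p0$assignment == "object", p0$activity_max > 0)
  taus <- c(0, 0.5, 1, 2, 4, 8)
  n_head <- vapply(taus, function(t)
    sum(parse_surfaces(surfaces, t, maps = maps)$assignment == "heading"),
    numeric(1))
  expect_true(all(diff(n_head) >= 0))
})

test_that("ground-truth source labels match brute-force sample membership", {
  sc0 <- build_scene(NULL, seed = 43)
  g0 <- layer2_group(layer1_average(sc0$combined))
  expect_false(any(ground_truth_source(g0)))
  lay <- list(radius = 2, eccentricity = 0, direction = 0)
  sc <- build_scene(lay, lambda = 0, H = 0.25, seed = 44)
  rep1 <- layer1_average(sc$combined)
  groups <- layer2_group(rep1)
  truth <- ground_truth_source(groups)
  oracle <- vapply(groups, function(g) any(rep1$n_object[g$members] > 0),
                   logical(1))
  expect_identical(truth, oracle)
  # the object sits near the heading: central groups must contain it
  cen <- which.min(vapply(groups, function(g) sum(g$center^2), numeric(1)))
  expect_true(truth[cen])
})
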