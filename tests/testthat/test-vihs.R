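# Anchor rectangle, vertex scattering, and the ViHS spline fit.

test_that("minimal-area rectangle handles squares and rotations exactly", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  r <- min_area_rect(wound_edge(sq))
  expect_equal(abs(woundmetrics:::polygon_signed_area(r$corners)), 1,
               tolerance = 1e-9)
  expect_equal(r$angle %% 90, 0, tolerance = 1e-7)
  # rotating by 45 degrees preserves the area and reports the rotation
  th <- pi / 4
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  r45 <- min_area_rect(wound_edge(sq %*% t(R)))
  expect_equal(abs(woundmetrics:::polygon_signed_area(r45$corners)), 1,
               tolerance = 1e-9)
  expect_equal(r45$angle %% 90, 45, tolerance = 1e-7)
})

test_that("minimal-area rectangle matches the exhaustive hull-edge oracle", {
  # independent oracle: try every convex-hull edge orientation by brute force
  oracle_area <- function(xy) {
    h <- xy[grDevices::chull(xy), , drop = FALSE]
    nh <- nrow(h)
    best <- Inf
    for (i in seq_len(nh)) {
      e <- h[(i %% nh) + 1, ] - h[i, ]
      a <- atan2(e[2], e[1])
      s1 <- h[, 1] * cos(a) + h[, 2] * sin(a)
      s2 <- -h[, 1] * sin(a) + h[, 2] * cos(a)
      best <- min(best, diff(range(s1)) * diff(range(s2)))
    }
    best
  }
  set.seed(21)
  for (rep in 1:8) {
    xy <- cbind(runif(200, -5, 9), rnorm(200, 2, 3))
    r <- min_area_rect(wound_edge(xy))
    expect_equal(abs(woundmetrics:::polygon_signed_area(r$corners)),
                 oracle_area(xy), tolerance = 1e-9)
    # containment: all points inside or on the rectangle
    inv <- woundmetrics:::bilinear_invert(r$corners, xy[, 1], xy[, 2])
    expect_true(all(inv$u > -1e-7 & inv$u < 1 + 1e-7 &
                      inv$v > -1e-7 & inv$v < 1 + 1e-7))
  }
  expect_error(min_area_rect(wound_edge(cbind(1:5, 2 * (1:5)))),
               class = "wm_degenerate_geometry")
})

test_that("min-area rectangle is rotation- and translation-equivariant", {
  set.seed(33)
  xy <- cbind(runif(60, 0, 20), runif(60, 0, 12))
  a0 <- abs(woundmetrics:::polygon_signed_area(min_area_rect(wound_edge(xy))$corners))
  for (th in c(0.3, 1.2, 2.5)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    xy2 <- sweep(xy %*% t(R), 2, c(7, -3), "+")
    a1 <- abs(woundmetrics:::polygon_signed_area(min_area_rect(wound_edge(xy2))$corners))
    expect_equal(a1, a0, tolerance = 1e-9)
  }
})

test_that("vertex scattering stays inside the 5 x 5 mm square, uniformly", {
  rect <- min_area_rect(wound_edge(cbind(c(0, 30, 30, 0), c(0, 0, 18, 18))))
  # zero half-width: all quads identical to the rectangle
  qs0 <- scatter_quads(rect, n = 5, half_width = 0, seed = 2)
  for (q in qs0) expect_equal(q$corners, rect$corners, tolerance = 1e-12)
  # displacements bounded by the half-width in the rectangle frame
  qs <- scatter_quads(rect, n = 2500, half_width = 2.5, seed = 3)
  d <- do.call(rbind, lapply(qs, function(q)
    (q$corners - rect$corners) %*% t(rect$axes)))
  expect_lt(max(abs(d)), 2.5 + 1e-12)
  # per-axis displacements pass a KS uniformity test against U(-2.5, 2.5)
  qs2 <- scatter_quads(rect, n = 12500, half_width = 2.5, seed = 4)
  d2 <- do.call(rbind, lapply(qs2, function(q)
    (q$corners - rect$corners) %*% t(rect$axes)))
  expect_gt(suppressWarnings(
    stats::ks.test(d2[, 1], "punif", -2.5, 2.5)$p.value), 0.01)
  expect_gt(suppressWarnings(
    stats::ks.test(d2[, 2], "punif", -2.5, 2.5)$p.value), 0.01)
  # reproducibility
  expect_identical(scatter_quads(rect, n = 4, seed = 9),
                   scatter_quads(rect, n = 4, seed = 9))
})

test_that("ViHS reproduces a plane to numerical precision", {
  spec <- synthetic_wound_spec(
    footprint_mm = c(50, 50), pitch_mm = 0.5, cyl_radius_mm = 1e9,
    undulation_amp_mm = 0, noise_sd_mm = 0, a_mm = 10, b_mm = 8,
    depth_mm = 2, taper_mm = 3, seed = 1)
  g <- synth_generate(spec, truth = FALSE)
  # shift the plane to z = 10 to make the check non-trivial
  srf <- g$wounded; srf$z <- srf$z + 10
  e <- mask_to_edge(g$true_mask, srf)
  vs <- fit_vihs(srf, g$true_mask, min_area_rect(e))
  u <- rep(seq(0, 1, length.out = 50), 50)
  v <- rep(seq(0, 1, length.out = 50), each = 50)
  # the wound region has z < 10; ViHS must bridge it at exactly 10
  zz <- woundmetrics:::vihs_eval_uv(vs, u, v)$z
  expect_lt(max(abs(zz - 10)), 1e-6)
})

test_that("ViHS bridges a wound on a cylinder to better than 0.1 mm RMS", {
  spec <- synthetic_wound_spec(
    footprint_mm = c(56, 56), pitch_mm = 0.25, cyl_radius_mm = 50,
    undulation_amp_mm = 0, noise_sd_mm = 0, a_mm = 10, b_mm = 10,
    depth_mm = 3, taper_mm = 3, seed = 1)
  g <- synth_generate(spec, truth = FALSE)
  e <- mask_to_edge(g$true_mask, g$wounded)
  vs <- fit_vihs(g$wounded, g$true_mask, min_area_rect(e))
  set.seed(5)
  th <- runif(4000) * 2 * pi; rr <- sqrt(runif(4000)) * 10
  x <- 28 + rr * cos(th); y <- 28 + rr * sin(th)
  zt <- woundmetrics:::base_z(spec, x, y)
  pz <- predict(vs, x, y)$z
  expect_lt(sqrt(mean((pz - zt)^2, na.rm = TRUE)), 0.1)
})

test_that("on wound-free skin the ViHS residual stays below the noise level", {
  spec <- synthetic_wound_spec(
    footprint_mm = c(50, 50), pitch_mm = 0.25, cyl_radius_mm = 60,
    noise_sd_mm = 0.05, a_mm = 8, b_mm = 8, depth_mm = 1, taper_mm = 2,
    seed = 6)
  g <- synth_generate(spec, truth = FALSE)
  srf <- g$healthy  # no wound carved
  empty <- matrix(FALSE, srf$rows, srf$cols)
  # anchor a quad roughly where the wound would have been
  quad <- min_area_rect(wound_edge(cbind(c(17, 33, 33, 17), c(17, 17, 33, 33))))
  vs <- fit_vihs(srf, empty, quad)
  xx <- rep(seq(18, 32, length.out = 40), 40)
  yy <- rep(seq(18, 32, length.out = 40), each = 40)
  res <- predict(vs, xx, yy)$z - woundmetrics:::surface_z_at(srf, xx, yy)
  expect_lt(sqrt(mean(res^2, na.rm = TRUE)), 0.05)
})

test_that("the instance ensemble is 1 + n, ordered and reproducible", {
  g <- flat_wound()
  e <- mask_to_edge(g$true_mask, g$wounded)
  insts <- build_instances(g$wounded, g$true_mask, e, n = 4, seed = 3)
  expect_length(insts, 5)
  expect_equal(insts[[1]]$anchor$provenance, "initial")
  expect_true(all(vapply(insts[-1], function(v) v$anchor$provenance,
                         character(1)) == "scattered"))
  insts0 <- build_instances(g$wounded, g$true_mask, e, n = 0)
  expect_length(insts0, 1)
  # zero scatter: all control nets numerically identical
  instz <- build_instances(g$wounded, g$true_mask, e, n = 6, half_width = 0,
                           seed = 3)
  spread <- max(vapply(instz[-1], function(v)
    max(abs(v$ctrl - instz[[1]]$ctrl)), numeric(1)))
  expect_lt(spread, 1e-9)
})
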