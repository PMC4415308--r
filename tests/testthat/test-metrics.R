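# Deviation field, VDW integration, perimeter/area, aggregation, statistics.

# plane surface + plane ViHS helper: build a flat organized surface with an
# optional rectangular depression, and fit a ViHS over a given anchor quad
flat_setup <- function(extent = 40, pitch = 0.25, depress = NULL, depth = 2,
                       tilt = c(0, 0)) {
  xc <- seq(0, extent, by = pitch); yc <- seq(0, extent, by = pitch)
  z <- outer(tilt[2] * yc, tilt[1] * xc, "+")
  if (!is.null(depress)) {
    # half-open cell selection: with the bilinear ramp at the walls the
    # effective prism footprint is exactly depress[3]-depress[1] wide
    ri <- yc >= depress[2] & yc < depress[4]
    ci <- xc >= depress[1] & xc < depress[3]
    z[ri, ci] <- z[ri, ci] - depth
  }
  organized_surface(xc, yc, z)
}

fit_plane_vihs <- function(srf, quad_xy, mask = NULL) {
  if (is.null(mask)) mask <- matrix(FALSE, srf$rows, srf$cols)
  fit_vihs(srf, mask, min_area_rect(wound_edge(quad_xy)), margin_mm = 0)
}

test_that("deviation field is zero when the surface is its own ViHS", {
  srf <- flat_setup()
  vs <- fit_plane_vihs(srf, cbind(c(5, 35, 35, 5), c(5, 5, 35, 35)))
  edge <- wound_edge(cbind(c(15, 25, 25, 15), c(15, 15, 25, 25)))
  fld <- deviation_field(srf, vs, edge, h = 0.25)
  expect_lt(max(abs(fld$d), na.rm = TRUE), 1e-6)
})

test_that("a square depression yields d = -depth inside and 0 outside", {
  srf <- flat_setup(depress = c(15, 15, 25, 25), depth = 2)
  mask <- matrix(FALSE, srf$rows, srf$cols)
  mask[srf$ycoord >= 14 & srf$ycoord <= 26, srf$xcoord >= 14 & srf$xcoord <= 26] <- TRUE
  vs <- fit_plane_vihs(srf, cbind(c(5, 35, 35, 5), c(5, 5, 35, 35)), mask)
  edge <- wound_edge(cbind(c(14, 26, 26, 14), c(14, 14, 26, 26)))
  fld <- deviation_field(srf, vs, edge, h = 0.25)
  inside <- fld$in_wound
  core <- outer(fld$yg >= 16, fld$xg >= 16) & outer(fld$yg <= 24, fld$xg <= 24)
  expect_lt(max(abs(fld$d[core & inside] + 2)), 1e-6)
  outside <- fld$in_domain & !inside &
    !(outer(fld$yg >= 14.5, fld$xg >= 14.5) & outer(fld$yg <= 25.5, fld$xg <= 25.5))
  expect_lt(max(abs(fld$d[outside]), na.rm = TRUE), 1e-6)
})

test_that("area elements carry the metric factor of a tilted ViHS", {
  # plane z = tan(30 deg) * x: area element must be h^2 / cos(30 deg)
  srf <- flat_setup(tilt = c(tan(pi / 6), 0))
  vs <- fit_plane_vihs(srf, cbind(c(5, 35, 35, 5), c(5, 5, 35, 35)))
  edge <- wound_edge(cbind(c(15, 25, 25, 15), c(15, 15, 25, 25)))
  fld <- deviation_field(srf, vs, edge, h = 0.25)
  ae <- fld$area_el[fld$in_wound]
  expect_lt(max(abs(ae - 0.25^2 / cos(pi / 6))) / (0.25^2 / cos(pi / 6)), 1e-6)
})

test_that("VDW of a 10 x 10 x 2 mm prism cavity is 200 mm^3", {
  srf <- flat_setup(depress = c(15, 15, 25, 25), depth = 2)
  mask <- matrix(FALSE, srf$rows, srf$cols)
  mask[srf$ycoord >= 14 & srf$ycoord <= 26, srf$xcoord >= 14 & srf$xcoord <= 26] <- TRUE
  vs <- fit_plane_vihs(srf, cbind(c(5, 35, 35, 5), c(5, 5, 35, 35)), mask)
  # wound edge placed between the prism wall and the flat rim
  edge <- wound_edge(cbind(c(14.5, 25.3, 25.3, 14.5), c(14.5, 14.5, 25.3, 25.3)))
  fld <- deviation_field(srf, vs, edge, h = 0.25)
  vv <- integrate_vdw(fld)
  expect_lt(abs(vv$vdw - 200) / 200, 0.01)
  expect_equal(vv$vdw, vv$v_pos + abs(vv$v_neg))
  expect_lte(vv$v_neg, 0)
  expect_gte(vv$v_pos, 0)
})

test_that("equal depression and protrusion integrate to v_pos = -v_neg = V", {
  srf <- flat_setup()
  # cosine bump up at (13,20), equal bump down at (27,20)
  X <- matrix(srf$xcoord, srf$rows, srf$cols, byrow = TRUE)
  Y <- matrix(srf$ycoord, srf$rows, srf$cols)
  bump <- function(cx, cy, r0, A) {
    d <- sqrt((X - cx)^2 + (Y - cy)^2)
    ifelse(d < r0, A * (1 + cos(pi * d / r0)) / 2, 0)
  }
  srf$z <- srf$z + bump(13, 20, 5, 1.5) - bump(27, 20, 5, 1.5)
  # mask out both bumps so the ViHS is fitted to the flat remainder
  mask <- sqrt((X - 13)^2 + (Y - 20)^2) < 5.5 |
    sqrt((X - 27)^2 + (Y - 20)^2) < 5.5
  vs <- fit_plane_vihs(srf, cbind(c(4, 36, 36, 4), c(10, 10, 30, 30)), mask)
  edge <- wound_edge(cbind(c(6, 34, 34, 6), c(12, 12, 28, 28)))
  fld <- deviation_field(srf, vs, edge, h = 0.25)
  vv <- integrate_vdw(fld)
  # fine-grid oracle at h/8 for the cosine bump volume
  hh <- 0.25 / 8
  gx <- seq(0, 40, by = hh)
  V <- 0
  for (cx in 13) {
    d <- sqrt(outer((gx - 20)^2, (gx - cx)^2, "+"))
    V <- sum(ifelse(d < 5, 1.5 * (1 + cos(pi * d / 5)) / 2, 0)) * hh^2
  }
  expect_lt(abs(vv$v_pos - V) / V, 0.01)
  expect_lt(abs(abs(vv$v_neg) - V) / V, 0.01)
  expect_lt(abs(vv$vdw - 2 * V) / (2 * V), 0.01)
})

test_that("halving the integration step changes VDW by less than 0.5%", {
  g <- curved_wound()
  res <- analyze(g$wounded, g$true_mask, wound_config(),
                 scatter = list(n = 0L))
  res2 <- analyze(g$wounded, g$true_mask, wound_config(),
                  scatter = list(n = 0L), integration = list(h = 0.125))
  v1 <- res$summary$mean[3]; v2 <- res2$summary$mean[3]
  expect_lt(abs(v1 - v2) / v2, 0.005)
})

test_that("perimeter and area of a circle on a flat ViHS match closed forms", {
  srf <- flat_setup()
  vs <- fit_plane_vihs(srf, cbind(c(5, 35, 35, 5), c(5, 5, 35, 35)))
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  edge <- wound_edge(cbind(20 + 10 * cos(th), 20 + 10 * sin(th)))
  fld <- deviation_field(srf, vs, edge, h = 0.25)
  pa <- measure_perimeter_area(vs, edge, fld)
  expect_lt(abs(pa$perimeter - 2 * pi * 10) / (2 * pi * 10), 0.005)
  expect_lt(abs(pa$area - pi * 100) / (pi * 100), 0.01)
})

test_that("a tilted ViHS doubles the area of a square at 60 degrees", {
  # plane z = tan(60 deg) * x: 10 mm square -> area 200 mm^2, perimeter 60 mm
  srf <- flat_setup(extent = 30, tilt = c(tan(pi / 3), 0))
  vs <- fit_plane_vihs(srf, cbind(c(5, 25, 25, 5), c(5, 5, 25, 25)))
  edge <- wound_edge(cbind(c(10, 20, 20, 10), c(10, 10, 20, 20)))
  fld <- deviation_field(srf, vs, edge, h = 0.25)
  pa <- measure_perimeter_area(vs, edge, fld)
  expect_lt(abs(pa$area - 200) / 200, 0.01)
  expect_lt(abs(pa$perimeter - 60) / 60, 0.005)
})

test_that("similarity scaling scales perimeter by 2 and area by 4", {
  mk <- function(scale) {
    srf <- flat_setup(extent = 40 * scale)
    vs <- fit_plane_vihs(srf, scale * cbind(c(5, 35, 35, 5), c(5, 5, 35, 35)))
    th <- seq(0, 2 * pi, length.out = 361)[-361]
    edge <- wound_edge(scale * cbind(20 + 8 * cos(th), 20 + 6 * sin(th)))
    fld <- deviation_field(srf, vs, edge, h = 0.25 * scale)
    measure_perimeter_area(vs, edge, fld)
  }
  p1 <- mk(1); p2 <- mk(2)
  expect_equal(p2$perimeter / p1$perimeter, 2, tolerance = 0.01)
  expect_equal(p2$area / p1$area, 4, tolerance = 0.01)
})

test_that("zero scatter makes all 31 instances agree to numerical precision", {
  g <- flat_wound()
  res <- analyze(g$wounded, g$true_mask, wound_config(),
                 scatter = list(n = 30L, half_width_mm = 0))
  expect_equal(res$n_instances, 31)
  expect_lt(res$summary$sd[1], 1e-6)
  expect_lt(res$summary$sd[2], 1e-6)
  expect_lt(res$summary$sd[3], 1e-6)
})

test_that("analysis summary is recomputable from the instance table", {
  g <- flat_wound()
  res <- analyze(g$wounded, g$true_mask, wound_config(), scatter = list(n = 5L))
  expect_equal(res$summary$mean[1], mean(res$instances$perimeter))
  expect_equal(res$summary$sd[3], sd(res$instances$vdw))
  expect_true(all(res$instances$vdw ==
                    res$instances$v_pos + abs(res$instances$v_neg)))
})

test_that("repeatability statistics behave like the underlying tests", {
  # identical groups: no location difference detectable
  gsame <- list(c(1, 2, 3, 4), c(1, 2, 3, 4), c(1, 2, 3, 4))
  r <- repeatability_stats(gsame)
  expect_gte(r$kruskal_p, 0.99)
  expect_equal(r$conf_level, 0.95)
  # well-separated groups: decisive rejection, matching a rank-sum oracle
  set.seed(8)
  a <- rnorm(20); b <- rnorm(20, 5)
  r2 <- repeatability_stats(list(a, b))
  expect_lt(r2$kruskal_p, 0.001)
  # two-group Kruskal-Wallis is equivalent to a Wilcoxon rank-sum test
  expect_equal(r2$kruskal_p,
               stats::kruskal.test(list(a, b))$p.value, tolerance = 1e-12)
  # order of groups is irrelevant
  r3 <- repeatability_stats(list(b, a))
  expect_equal(r2$kruskal_p, r3$kruskal_p)
  expect_equal(r2$levene_p, r3$levene_p)
  expect_error(repeatability_stats(list(1:3)), class = "wm_stats_insufficient")
  expect_error(repeatability_stats(list(1, 2)), class = "wm_stats_insufficient")
})
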