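# The three wound-edge back-ends.

make_disk_image <- function(n = 100, r = 40, fg = c(170, 60, 55),
                            bg = c(205, 168, 150), noise = 4, seed = 5) {
  set.seed(seed)
  rgb <- array(0L, dim = c(n, n, 3))
  d <- outer((1:n) - n / 2, (1:n) - n / 2, function(a, b) sqrt(a^2 + b^2))
  inside <- d <= r
  for (k in 1:3) {
    ch <- ifelse(inside, fg[k], bg[k]) + rnorm(n * n, 0, noise)
    rgb[, , k] <- as.integer(round(pmin(pmax(ch, 0), 255)))
  }
  structure(list(rows = n, cols = n, rgb = rgb,
                 valid = matrix(TRUE, n, n)), class = "color_image")
}

test_that("CED recovers a color disk to within 5% area", {
  img <- make_disk_image()
  m <- segment_ced(img, channel = "G")
  expect_lt(abs(sum(m) - pi * 40^2) / (pi * 40^2), 0.05)
})

test_that("CED on a uniform image reports an unclosed edge", {
  rgb <- array(128L, dim = c(50, 50, 3))
  img <- structure(list(rows = 50, cols = 50, rgb = rgb,
                        valid = matrix(TRUE, 50, 50)), class = "color_image")
  expect_error(segment_ced(img, channel = "gray"),
               class = "wm_edge_not_closed")
})

test_that("raising t_high never increases the Canny edge-pixel count", {
  img <- make_disk_image(seed = 9)
  ch <- woundmetrics:::color_channel(img, "G")
  counts <- vapply(c(0.15, 0.3, 0.5, 0.7),
                   function(th) sum(woundmetrics:::canny_edges(ch, 0.1, th, 1.4)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("manual strokes can close a broken edge", {
  # disk whose rim gradient fades below threshold over one quadrant:
  # the Canny contour is an open arc until the operator closes it
  n <- 100; r <- 40; fg <- c(170, 60, 55); bg <- c(205, 168, 150)
  rgb <- array(0L, dim = c(n, n, 3))
  rowi <- matrix(1:n, n, n); coli <- matrix(1:n, n, n, byrow = TRUE)
  d <- sqrt((rowi - n / 2)^2 + (coli - n / 2)^2)
  th <- atan2(rowi - n / 2, coli - n / 2) %% (2 * pi)
  width <- ifelse(th > 3 * pi / 2, 14, 1)
  w <- 1 / (1 + exp((d - r) / width))
  for (k in 1:3)
    rgb[, , k] <- as.integer(round(w * fg[k] + (1 - w) * bg[k]))
  img <- structure(list(rows = n, cols = n, rgb = rgb,
                        valid = matrix(TRUE, n, n)), class = "color_image")
  expect_error(segment_ced(img, channel = "G", gap_max = 0, close_radius = 1),
               class = "wm_edge_not_closed")
  ang <- seq(3 * pi / 2, 2 * pi, length.out = 30)
  strokes <- list(cbind(n / 2 + r * sin(ang), n / 2 + r * cos(ang)))
  m <- segment_ced(img, channel = "G", gap_max = 0, close_radius = 1,
                   manual_strokes = strokes)
  expect_gt(sum(m), 0.8 * pi * r^2)
  expect_lt(sum(m), 1.2 * pi * r^2)
})

test_that("GrowCut with every pixel seeded is a fixed point", {
  f <- seg_fixture()
  s <- matrix(2L, f$img$rows, f$img$cols)
  s[f$g$true_mask] <- 1L
  m <- segment_growcut(f$img, seed_labels(s))
  expect_identical(unname(m > 0), unname(f$g$true_mask & f$img$valid))
})

test_that("GrowCut on two uniform half-planes matches the color boundary and a brute-force automaton", {
  n <- 20
  rgb <- array(0L, dim = c(n, n, 3))
  rgb[, 1:10, ] <- 60L; rgb[, 11:20, ] <- 200L
  img <- structure(list(rows = n, cols = n, rgb = rgb,
                        valid = matrix(TRUE, n, n)), class = "color_image")
  s <- matrix(0L, n, n); s[10, 3] <- 1L; s[10, 17] <- 2L
  m <- segment_growcut(img, seed_labels(s))
  attr(m, "converged") <- NULL
  expect_identical(unname(m), unname(col(matrix(0, n, n)) <= 10))
  # independent brute-force automaton (plain loops, same update rule)
  lab <- s; theta <- matrix(0, n, n); theta[s > 0] <- 1
  dmax <- sqrt(3) * 255
  px <- function(i, j, k) rgb[i, j, k]
  for (it in 1:200) {
    lab2 <- lab; th2 <- theta; changed <- FALSE
    for (i in 1:n) for (j in 1:n) {
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        qi <- i + di; qj <- j + dj
        if (qi < 1 || qi > n || qj < 1 || qj > n) next
        if (lab[qi, qj] == 0L) next
        dd <- sqrt(sum((rgb[i, j, ] - rgb[qi, qj, ])^2))
        cand <- (1 - dd / dmax) * theta[qi, qj]
        if (cand > th2[i, j]) {
          th2[i, j] <- cand; lab2[i, j] <- lab[qi, qj]; changed <- TRUE
        }
      }
    }
    lab <- lab2; theta <- th2
    if (!changed) break
  }
  expect_identical(unname(m), unname(lab == 1L))
})

test_that("GrowCut converges deterministically and never relabels seeds", {
  f <- seg_fixture()
  m1 <- segment_growcut(f$img, f$seeds)
  m2 <- segment_growcut(f$img, f$seeds)
  expect_true(attr(m1, "converged"))
  expect_identical(m1, m2)
  expect_true(all(m1[f$seeds == 1L]))
  expect_true(all(!m1[f$seeds == 2L]))
  expect_error(segment_growcut(f$img, seed_labels(matrix(1L, f$img$rows, f$img$cols))),
               class = "wm_seed_missing")
})

test_that("GrabCut respects hard constraints over random seedings", {
  f <- seg_fixture()
  # all pixels hard-labeled -> output equals the seeding
  s <- matrix(2L, f$img$rows, f$img$cols)
  s[f$g$true_mask] <- 1L
  m <- segment_grabcut(f$img, seed_labels(s), seed = 1)
  expect_identical(unname(m > 0), unname(f$g$true_mask & f$img$valid))
  # background-seeded pixels never end up as wound
  img <- make_disk_image(n = 40, r = 14)
  set.seed(100)
  for (rep in 1:25) {
    s <- matrix(0L, 40, 40)
    nfg <- sample(3:20, 1); nbg <- sample(3:20, 1)
    d <- outer((1:40) - 20, (1:40) - 20, function(a, b) sqrt(a^2 + b^2))
    fg_pool <- which(d < 10); bg_pool <- which(d > 17)
    s[sample(fg_pool, nfg)] <- 1L
    s[sample(bg_pool, nbg)] <- 2L
    m <- segment_grabcut(img, seed_labels(s), n_iter = 2, seed = rep)
    expect_true(all(!m[s == 2L]))
  }
})

test_that("all three back-ends recover the generator wound with high overlap", {
  f <- seg_fixture()
  m_ced <- segment_ced(f$img, channel = "G")
  m_gro <- segment_growcut(f$img, f$seeds)
  m_gra <- segment_grabcut(f$img, f$seeds, seed = 1)
  expect_gt(jaccard(m_ced, f$g$true_mask), 0.9)
  expect_gt(jaccard(m_gro, f$g$true_mask), 0.9)
  expect_gt(jaccard(m_gra, f$g$true_mask), 0.95)
  # deterministic reruns are bit-identical
  expect_identical(m_gra, segment_grabcut(f$img, f$seeds, seed = 1))
})
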