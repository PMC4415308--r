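# Wound masks and closed edge polylines: component selection, Moore boundary
# tracing, polygon rasterization, contour smoothing, point-in-polygon.

#' Closed wound-edge polyline
#'
#' @param xy n x 2 matrix of physical vertex positions (mm), ordered along the
#'   contour; the polygon is implicitly closed (last vertex connects to the
#'   first).
#' @param rc optional n x 2 matrix of (row, col) grid positions (possibly
#'   fractional) matching `xy`.
#' @return Object of class `wound_edge`.
#' @export
wound_edge <- function(xy, rc = NULL) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 3L) wm_stop("wm_empty_mask", "edge needs at least 3 vertices")
  structure(list(xy = xy, rc = if (!is.null(rc)) as.matrix(rc) else NULL),
            class = "wound_edge")
}

#' @export
print.wound_edge <- function(x, ...) {
  cat(sprintf("wound_edge: %d vertices, perimeter (xy plane) %.2f mm\n",
              nrow(x$xy), polyline_length(x$xy, closed = TRUE)))
  invisible(x)
}

polyline_length <- function(p, closed = FALSE) {
  if (closed) p <- rbind(p, p[1L, , drop = FALSE])
  sum(sqrt(rowSums(diff(p)^2)))
}

polygon_signed_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  x2 <- c(x[-1L], x[1L]); y2 <- c(y[-1L], y[1L])
  sum(x * y2 - x2 * y) / 2
}

# vectorized even-odd (crossing number) point-in-polygon;
# points on a horizontal edge handled by the half-open convention
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  for (i in seq_len(n)) {
    cross <- ((y1[i] > py) != (y2[i] > py)) &
      (px < (x2[i] - x1[i]) * (py - y1[i]) / (y2[i] - y1[i]) + x1[i])
    inside <- xor(inside, cross & !is.na(cross))
  }
  inside
}

# --- mask utilities ---------------------------------------------------------

# keep the largest 4-connected foreground component of a logical matrix
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask * 1)))))
  tab <- tabulate(lab[lab > 0])
  mask & (lab == which.max(tab))
}

fill_holes <- function(mask) {
  f <- EBImage::fillHull(EBImage::Image(t(mask * 1)))
  t(EBImage::imageData(f)) > 0
}

clean_mask <- function(mask, fill = TRUE) {
  m <- largest_component(mask)
  if (fill) m <- fill_holes(m)
  m
}

#' Trace the wound edge of a binary mask
#'
#' Keeps the largest 4-connected foreground component, fills interior holes
#' (the wound edge is a single outer contour), and traces its boundary
#' clockwise with Moore-neighbor tracing. Consecutive vertices are 8-grid
#' neighbors.
#'
#' @param mask logical matrix (rows x cols).
#' @param surface optional [organized_surface()] supplying physical xy; if
#'   omitted, xy are (col, row) in pixel units.
#' @return A [wound_edge()] with `rc` grid vertices and physical `xy`.
#' @export
mask_to_edge <- function(mask, surface = NULL) {
  mask <- as.matrix(mask) > 0
  if (!any(mask)) wm_stop("wm_empty_mask", "mask is empty")
  mask <- clean_mask(mask)
  rc <- trace_boundary(mask)
  if (nrow(rc) < 3L)
    wm_stop("wm_empty_mask", "component too small for a closed contour")
  xy <- if (!is.null(surface)) surface_xy_at(surface, rc)
        else cbind(x = rc[, 2L], y = rc[, 1L])
  wound_edge(xy, rc)
}

# Moore-neighbor boundary tracing (clockwise radial sweep around the current
# pixel, restarting from the last background cell examined); terminates when
# the initial (pixel, backtrack) state recurs
trace_boundary <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- mask
  start <- which(pad, arr.ind = TRUE)
  start <- start[order(start[, 1L], start[, 2L]), , drop = FALSE][1L, ]
  # clockwise Moore neighborhood (compass W, NW, N, NE, E, SE, S, SW)
  nb <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
              c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  dir_of <- function(delta) {
    which(nb[, 1L] == delta[1L] & nb[, 2L] == delta[2L])
  }
  cur <- start
  back <- start + nb[1L, ]  # west neighbor: background for the topmost-leftmost pixel
  out <- matrix(0L, 8L * sum(pad) + 8L, 2L)
  out[1L, ] <- cur; m <- 1L
  state0 <- c(cur, back)
  repeat {
    d0 <- dir_of(back - cur)
    nxt <- NULL
    for (k in 1:8) {
      d <- ((d0 - 1L + k) %% 8L) + 1L
      cand <- cur + nb[d, ]
      if (pad[cand[1L], cand[2L]]) {
        dprev <- ((d0 - 1L + k - 1L) %% 8L) + 1L
        nxt <- cand
        back <- cur + nb[dprev, ]  # last background cell examined
        break
      }
    }
    if (is.null(nxt)) break  # isolated single pixel
    cur <- nxt
    if (all(c(cur, back) == state0)) break
    m <- m + 1L
    out[m, ] <- cur
    if (m >= nrow(out)) break  # safety
  }
  res <- out[seq_len(m), , drop = FALSE] - 1L
  colnames(res) <- c("r", "c")
  res
}

#' Rasterize a closed edge into a binary mask
#'
#' Even-odd (crossing-number) fill evaluated at pixel centers; pixels whose
#' centers lie on the polygon boundary are included, so an axis-aligned
#' square edge through pixel centers yields a boundary-inclusive fill.
#' Self-intersecting edges are filled even-odd with a warning.
#'
#' @param edge a [wound_edge()] with grid `rc` vertices.
#' @param rows,cols output mask dimensions.
#' @return Logical `rows x cols` matrix.
#' @export
edge_to_mask <- function(edge, rows, cols) {
  stopifnot(inherits(edge, "wound_edge"))
  rc <- edge$rc
  if (is.null(rc)) wm_stop("wm_format_error", "edge carries no grid coordinates")
  if (!polygon_is_simple(rc)) wm_warn("self-intersecting edge; even-odd fill applied")
  rr <- range(rc[, 1L]); cr <- range(rc[, 2L])
  ri <- max(1L, floor(rr[1L])):min(rows, ceiling(rr[2L]))
  ci <- max(1L, floor(cr[1L])):min(cols, ceiling(cr[2L]))
  g <- expand.grid(r = ri, c = ci)
  inside <- point_in_polygon(g$c, g$r, rc[, c(2L, 1L)])
  mask <- matrix(FALSE, rows, cols)
  mask[cbind(g$r, g$c)] <- inside
  # boundary-inclusive: pixels whose centers lie (numerically) on the contour
  dens <- densify_closed(rc, 0.25)
  br <- round(dens[, 1L]); bc <- round(dens[, 2L])
  onb <- abs(dens[, 1L] - br) < 1e-9 & abs(dens[, 2L] - bc) < 1e-9 &
    br >= 1 & br <= rows & bc >= 1 & bc <= cols
  mask[cbind(br[onb], bc[onb])] <- TRUE
  mask
}

# subdivide a closed polyline so consecutive points are at most `step` apart
densify_closed <- function(p, step) {
  q <- rbind(p, p[1L, , drop = FALSE])
  seg <- sqrt(rowSums(diff(q)^2))
  out <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    k <- max(1L, ceiling(seg[i] / step))
    t <- (seq_len(k) - 1L) / k
    out[[i]] <- cbind(q[i, 1L] + t * (q[i + 1L, 1L] - q[i, 1L]),
                      q[i, 2L] + t * (q[i + 1L, 2L] - q[i, 2L]))
  }
  do.call(rbind, out)
}

# O(n^2) segment-crossing test; adequate for <= a few thousand vertices
polygon_is_simple <- function(p) {
  n <- nrow(p)
  if (n > 2000L) return(TRUE)  # skip the quadratic test on long traced contours
  a <- p; b <- rbind(p[-1L, , drop = FALSE], p[1L, , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    js <- (i + 2L):n
    js <- js[!(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(a[i, ], b[i, ], a[js, , drop = FALSE],
                           b[js, , drop = FALSE]))) return(FALSE)
  }
  TRUE
}

segments_cross <- function(p1, p2, q1, q2) {
  d <- function(a, b, c) (b[, 1L] - a[, 1L]) * (c[, 2L] - a[, 2L]) -
    (b[, 2L] - a[, 2L]) * (c[, 1L] - a[, 1L])
  p1 <- matrix(p1, nrow(q1), 2L, byrow = TRUE)
  p2 <- matrix(p2, nrow(q1), 2L, byrow = TRUE)
  d1 <- d(q1, q2, p1); d2 <- d(q1, q2, p2)
  d3 <- d(p1, p2, q1); d4 <- d(p1, p2, q2)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Smooth and offset a traced wound edge
#'
#' A contour traced on the pixel grid carries two known measurement biases:
#' staircase excess length, and a half-pixel inward offset (the traced path
#' runs through the centers of the outermost foreground pixels). This helper
#' removes both: circular Gaussian smoothing of the vertex coordinates along
#' the contour, followed by an outward normal offset (typically half the grid
#' pitch). Analytic (sub-pixel) edges should not be passed through it.
#'
#' @param edge a [wound_edge()].
#' @param sigma smoothing bandwidth in vertex steps (approximately pixels for
#'   traced contours); 0 disables smoothing.
#' @param offset outward offset in mm; 0 disables.
#' @param resample_to approximate number of output vertices (contour is
#'   resampled uniformly in arc length first); `NULL` keeps all vertices.
#' @return A smoothed [wound_edge()] (grid `rc` preserved approximately via
#'   the same transform when present).
#' @export
smooth_edge <- function(edge, sigma = 2, offset = 0, resample_to = 400L) {
  stopifnot(inherits(edge, "wound_edge"))
  xy <- edge$xy
  n0 <- nrow(xy)
  scale_rc <- NULL
  if (!is.null(edge$rc) && n0 >= 3L) {
    # infer the xy-per-grid-step scale to transform rc consistently
    scale_rc <- c(
      stats::median(abs(diff(edge$xy[, 1L])[diff(edge$rc[, 2L]) != 0] /
                          diff(edge$rc[, 2L])[diff(edge$rc[, 2L]) != 0])),
      stats::median(abs(diff(edge$xy[, 2L])[diff(edge$rc[, 1L]) != 0] /
                          diff(edge$rc[, 1L])[diff(edge$rc[, 1L]) != 0])))
  }
  if (!is.null(resample_to) && n0 > resample_to) {
    s <- c(0, cumsum(sqrt(rowSums(diff(rbind(xy, xy[1L, ]))^2))))
    tt <- seq(0, s[length(s)], length.out = resample_to + 1L)[-(resample_to + 1L)]
    cx <- stats::approx(s, c(xy[, 1L], xy[1L, 1L]), xout = tt)$y
    cy <- stats::approx(s, c(xy[, 2L], xy[1L, 2L]), xout = tt)$y
    xy <- cbind(cx, cy)
    sigma <- sigma * resample_to / n0  # keep bandwidth fixed in arc length
  }
  n <- nrow(xy)
  if (sigma > 0) {
    half <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-half:half, sd = sigma)
    k <- k / sum(k)
    smooth1 <- function(v) {
      ext <- c(v[(n - half + 1L):n], v, v[1:half])
      stats::filter(ext, k, sides = 2)[(half + 1L):(half + n)]
    }
    xy <- cbind(smooth1(xy[, 1L]), smooth1(xy[, 2L]))
  }
  if (offset != 0) {
    nxt <- rbind(xy[-1L, ], xy[1L, ]); prv <- rbind(xy[n, ], xy[-n, ])
    tang <- nxt - prv
    len <- sqrt(rowSums(tang^2)); len[len == 0] <- 1
    nrm <- cbind(tang[, 2L], -tang[, 1L]) / len  # outward for a CCW polygon
    if (polygon_signed_area(xy) < 0) nrm <- -nrm  # make it point outward
    xy <- xy + offset * nrm
  }
  rc <- NULL
  if (!is.null(scale_rc) && all(is.finite(scale_rc)) && all(scale_rc > 0)) {
    ox <- edge$xy[1L, 1L] - scale_rc[1L] * edge$rc[1L, 2L]
    oy <- edge$xy[1L, 2L] - scale_rc[2L] * edge$rc[1L, 1L]
    rc <- cbind((xy[, 2L] - oy) / scale_rc[2L], (xy[, 1L] - ox) / scale_rc[1L])
  }
  wound_edge(xy, rc)
}
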