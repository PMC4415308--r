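# Virtual healthy skin (ViHS): anchor quad from the minimal-area rectangle
# circumscribed to the wound edge, scattered quad instances, and the spline
# surface approximating intact skin over the wound.

#' ViHS anchor quadrilateral
#'
#' @param corners 4 x 2 matrix of xy vertices (mm), counterclockwise.
#' @param axes 2 x 2 matrix whose rows are the rectangle's unit axes (used to
#'   orient scatter squares and margin expansion).
#' @param provenance `"initial"` or `"scattered"`.
#' @param angle orientation of the long axis, degrees in [0, 180).
#' @return Object of class `vihs_quad`.
#' @export
vihs_quad <- function(corners, axes = NULL, provenance = "initial",
                      angle = NA_real_) {
  corners <- as.matrix(corners)
  stopifnot(nrow(corners) == 4L, ncol(corners) == 2L)
  if (polygon_signed_area(corners) < 0) corners <- corners[4:1, ]
  if (!quad_is_simple(corners))
    wm_stop("wm_degenerate_geometry", "quad is self-intersecting")
  if (is.null(axes)) {
    e1 <- corners[2L, ] - corners[1L, ]
    e1 <- e1 / sqrt(sum(e1^2))
    axes <- rbind(e1, c(-e1[2L], e1[1L]))
  }
  structure(list(corners = corners, axes = axes, provenance = provenance,
                 angle = angle),
            class = "vihs_quad")
}

quad_is_simple <- function(p) {
  # a 4-gon is simple iff neither pair of opposite edges crosses
  !(any(segments_cross(p[1L, ], p[2L, ], p[3L, , drop = FALSE],
                       p[4L, , drop = FALSE])) ||
      any(segments_cross(p[2L, ], p[3L, ], p[4L, , drop = FALSE],
                         p[1L, , drop = FALSE])))
}

#' @export
print.vihs_quad <- function(x, ...) {
  cat(sprintf("vihs_quad (%s): area %.1f mm^2, long-axis angle %.1f deg\n",
              x$provenance, abs(polygon_signed_area(x$corners)), x$angle))
  invisible(x)
}

#' Minimal-area rectangle circumscribed to the wound edge
#'
#' Rotating-calipers construction: the minimal-area enclosing rectangle of a
#' planar point set has one side collinear with a convex-hull edge, so the
#' hull edges are scanned exhaustively. All edge points lie inside or on the
#' rectangle; corners are ordered counterclockwise starting at the corner
#' nearest the minimal (x, y), and the reported orientation of the long axis
#' lies in [0, 180) degrees.
#'
#' @param edge a [wound_edge()] (or n x 2 xy matrix).
#' @return A [vihs_quad()] with `provenance = "initial"`.
#' @export
min_area_rect <- function(edge) {
  xy <- if (inherits(edge, "wound_edge")) edge$xy else as.matrix(edge)
  if (nrow(xy) < 3L) wm_stop("wm_degenerate_geometry", "need >= 3 edge vertices")
  h <- grDevices::chull(xy)
  hull <- xy[h, , drop = FALSE]
  if (nrow(hull) < 3L)
    wm_stop("wm_degenerate_geometry", "edge vertices are collinear")
  nh <- nrow(hull)
  best <- NULL; best_area <- Inf
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len < 1e-12) next
    ex <- e / len; ey <- c(-ex[2L], ex[1L])
    s <- hull %*% cbind(ex, ey)
    w <- diff(range(s[, 1L])); hgt <- diff(range(s[, 2L]))
    area <- w * hgt
    if (area < best_area - 1e-12) {
      best_area <- area
      best <- list(ex = ex, ey = ey, smin = apply(s, 2L, min),
                   smax = apply(s, 2L, max))
    }
  }
  R <- rbind(best$ex, best$ey)  # rows are axes
  crn <- rbind(c(best$smin[1L], best$smin[2L]),
               c(best$smax[1L], best$smin[2L]),
               c(best$smax[1L], best$smax[2L]),
               c(best$smin[1L], best$smax[2L])) %*% R
  side <- c(best$smax[1L] - best$smin[1L], best$smax[2L] - best$smin[2L])
  long_axis <- if (side[1L] >= side[2L]) best$ex else best$ey
  ang <- (atan2(long_axis[2L], long_axis[1L]) * 180 / pi) %% 180
  # deterministic corner order: start nearest (min x, then min y)
  start <- order(round(crn[, 1L], 9), round(crn[, 2L], 9))[1L]
  crn <- crn[((start - 1L + 0:3) %% 4L) + 1L, ]
  if (polygon_signed_area(crn) < 0) crn <- crn[c(1L, 4L, 3L, 2L), ]
  e1 <- crn[2L, ] - crn[1L, ]; e1 <- e1 / sqrt(sum(e1^2))
  vihs_quad(crn, axes = rbind(e1, c(-e1[2L], e1[1L])),
            provenance = "initial", angle = ang)
}

#' Scatter the rectangle vertices to build an ensemble of anchor quads
#'
#' Each vertex of the anchor rectangle is displaced independently and
#' uniformly within a square of side `2 * half_width` (default 5 x 5 mm)
#' centered on the vertex and aligned with the rectangle's own axes,
#' mirroring the random-vertex robustification of the measurement. Quads
#' that become self-intersecting are redrawn.
#'
#' @param rect a [vihs_quad()] (typically from [min_area_rect()]).
#' @param n number of scattered quads (default 30).
#' @param half_width half-side of the scatter square (mm, default 2.5).
#' @param seed RNG seed; draws are reproducible given the seed.
#' @param max_retry redraw budget per quad.
#' @return List of `n` [vihs_quad()]s with `provenance = "scattered"`.
#' @export
scatter_quads <- function(rect, n = 30L, half_width = 2.5, seed = 1L,
                          max_retry = 100L) {
  stopifnot(inherits(rect, "vihs_quad"), half_width >= 0)
  R <- rect$axes  # rows: e1, e2
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    for (try in seq_len(max_retry)) {
      d <- matrix(stats::runif(8L, -half_width, half_width), 4L, 2L)
      crn <- rect$corners + d %*% R
      if (quad_is_simple(crn)) break
      if (try == max_retry)
        wm_stop("wm_scatter_failed", "could not draw a simple quad in %d tries",
                max_retry)
    }
    out[[i]] <- vihs_quad(crn, axes = R, provenance = "scattered",
                          angle = rect$angle)
  }
  out
}

# expand a quad outward by `margin` mm along the rectangle axes: corner k of
# a CCW quad moves by the sign pattern of a rectangle's corners
expand_quad <- function(quad, margin) {
  if (margin <= 0) return(quad)
  R <- quad$axes
  s1 <- c(-1, 1, 1, -1); s2 <- c(-1, -1, 1, 1)
  crn <- quad$corners + margin * (s1 %o% R[1L, ] + s2 %o% R[2L, ])
  vihs_quad(crn, axes = R, provenance = quad$provenance, angle = quad$angle)
}

#' Fit the virtual-healthy-skin surface over an anchor quad
#'
#' The spline domain is the anchor quad expanded outward by `margin_mm` along
#' the rectangle axes (so the boundary runs through healthy skin even though
#' the anchor rectangle is tangent to the wound edge, and the whole wound
#' stays inside the domain for inward-scattered vertices). The fit proceeds
#' in three stages: (1) the measured surface is sampled along each domain
#' edge, wound-covered or invalid samples replaced by arc-length linear
#' interpolation from flanking healthy samples, and a clamped cubic B-spline
#' curve is fitted to each edge; (2) the interior control net is initialized
#' as the discrete Coons patch of the four boundary curves; (3) interior
#' control points are refined by penalized least squares against the
#' non-wound valid cells inside the domain, with a thin-plate-style
#' smoothness penalty (boundary control points stay fixed). Stage (3) is
#' skipped when fewer than `min_samples` healthy cells are available.
#'
#' @param surface an [organized_surface()].
#' @param wound_mask logical matrix flagging wound cells.
#' @param quad a [vihs_quad()] anchor.
#' @param n_ctrl control points per direction (default 8).
#' @param degree spline degree (default 3, cubic).
#' @param lambda smoothness penalty weight (default 0.1).
#' @param margin_mm outward domain expansion (mm, default 5).
#' @param min_samples minimal healthy-cell count for the LS refinement.
#' @return Object of class `vihs_surface`: the domain quad, knot vectors and
#'   the z control net over the bilinear (u,v) -> (x,y) map.
#' @export
fit_vihs <- function(surface, wound_mask, quad, n_ctrl = 8L, degree = 3L,
                     lambda = 0.1, margin_mm = 5, min_samples = 50L) {
  stopifnot(inherits(surface, "organized_surface"), inherits(quad, "vihs_quad"))
  wound_mask <- as.matrix(wound_mask) > 0
  dom <- expand_quad(quad, margin_mm)
  P <- dom$corners
  knots <- open_uniform_knots(n_ctrl, degree)
  step <- min(surface$pitch_x, surface$pitch_y)

  sample_edge <- function(a, b) {
    len <- sqrt(sum((b - a)^2))
    m <- max(4L * n_ctrl, ceiling(len / step) + 1L)
    t <- seq(0, 1, length.out = m)
    x <- a[1L] + t * (b[1L] - a[1L]); y <- a[2L] + t * (b[2L] - a[2L])
    z <- surface_z_at(surface, x, y)
    cell <- surface_cell_at(surface, x, y)
    bad <- !is.finite(z) | wound_mask[cell] | !surface$valid[cell]
    if (all(bad))
      wm_stop("wm_vihs_underconstrained",
              "no healthy samples along a domain edge")
    if (any(bad))
      z[bad] <- stats::approx(t[!bad], z[!bad], xout = t[bad], rule = 2)$y
    list(t = t, z = z)
  }
  # domain edges: bottom (1->2, v=0), right (2->3, u=1),
  # top (4->3, v=1), left (1->4, u=0)
  eb <- sample_edge(P[1L, ], P[2L, ])
  er <- sample_edge(P[2L, ], P[3L, ])
  et <- sample_edge(P[4L, ], P[3L, ])
  el <- sample_edge(P[1L, ], P[4L, ])
  # consistent corner heights: average the two adjacent edge estimates
  zc <- c(mean(c(eb$z[1L], el$z[1L])),                      # (0,0)
          mean(c(eb$z[length(eb$z)], er$z[1L])),            # (1,0)
          mean(c(er$z[length(er$z)], et$z[length(et$z)])),  # (1,1)
          mean(c(et$z[1L], el$z[length(el$z)])))            # (0,1)
  cb <- fit_bspline_curve(eb$t, eb$z, knots, degree, zc[1L], zc[2L])
  cr <- fit_bspline_curve(er$t, er$z, knots, degree, zc[2L], zc[3L])
  ct <- fit_bspline_curve(et$t, et$z, knots, degree, zc[4L], zc[3L])
  cl <- fit_bspline_curve(el$t, el$z, knots, degree, zc[1L], zc[4L])
  # discrete Coons patch on the control net (Greville blending)
  gu <- greville(knots, degree); gv <- gu
  n <- n_ctrl
  C <- matrix(0, n, n)  # C[i, j]: i = u index, j = v index
  for (j in seq_len(n)) for (i in seq_len(n)) {
    C[i, j] <- (1 - gv[j]) * cb[i] + gv[j] * ct[i] +
      (1 - gu[i]) * cl[j] + gu[i] * cr[j] -
      ((1 - gu[i]) * (1 - gv[j]) * zc[1L] + gu[i] * (1 - gv[j]) * zc[2L] +
         gu[i] * gv[j] * zc[3L] + (1 - gu[i]) * gv[j] * zc[4L])
  }
  # penalized LS refinement of the interior control points
  bb_r <- range(P[, 2L]); bb_c <- range(P[, 1L])
  rows_in <- which(surface$ycoord >= bb_r[1L] & surface$ycoord <= bb_r[2L])
  cols_in <- which(surface$xcoord >= bb_c[1L] & surface$xcoord <= bb_c[2L])
  refined <- FALSE
  if (length(rows_in) && length(cols_in)) {
    g <- expand.grid(r = rows_in, c = cols_in)
    keep <- surface$valid[cbind(g$r, g$c)] & !wound_mask[cbind(g$r, g$c)]
    g <- g[keep, , drop = FALSE]
    if (nrow(g)) {
      xs <- surface$xcoord[g$c]; ys <- surface$ycoord[g$r]
      inv <- bilinear_invert(P, xs, ys)
      ins <- inv$converged & inv$u > 1e-9 & inv$u < 1 - 1e-9 &
        inv$v > 1e-9 & inv$v < 1 - 1e-9
      if (sum(ins) >= min_samples) {
        u <- inv$u[ins]; v <- inv$v[ins]
        zdat <- surface$z[cbind(g$r, g$c)][ins]
        Bu <- bspline_basis(knots, u, degree)
        Bv <- bspline_basis(knots, v, degree)
        # full design matrix, columns ordered as vec(C) (u index fastest)
        Bfull <- matrix(0, length(u), n * n)
        for (j in seq_len(n)) {
          cols <- ((j - 1L) * n + 1L):(j * n)
          Bfull[, cols] <- Bu * Bv[, j]
        }
        idx <- matrix(seq_len(n * n), n, n)
        fixed <- unique(c(idx[1L, ], idx[n, ], idx[, 1L], idx[, n]))
        free <- setdiff(seq_len(n * n), fixed)
        # thin-plate energy in physical units (domain-size invariant):
        # divided differences taken on mm-scaled Greville positions, energy
        # weighted by the domain area
        Lu <- 0.5 * (sqrt(sum((P[2L, ] - P[1L, ])^2)) +
                       sqrt(sum((P[3L, ] - P[4L, ])^2)))
        Lv <- 0.5 * (sqrt(sum((P[4L, ] - P[1L, ])^2)) +
                       sqrt(sum((P[3L, ] - P[2L, ])^2)))
        K <- ctrl_penalty(gu * Lu, gv * Lv) * (Lu * Lv)
        cvec <- as.numeric(C)
        rhs <- zdat - Bfull[, fixed, drop = FALSE] %*% cvec[fixed]
        Bf <- Bfull[, free, drop = FALSE]
        A <- crossprod(Bf) + lambda * K[free, free]
        b <- crossprod(Bf, rhs) - lambda * K[free, fixed] %*% cvec[fixed]
        cvec[free] <- solve(A, b)
        C <- matrix(cvec, n, n)
        refined <- TRUE
      }
    }
  }
  structure(list(domain = dom, anchor = quad, knots = knots, degree = degree,
                 ctrl = C, refined = refined),
            class = "vihs_surface")
}

#' @export
print.vihs_surface <- function(x, ...) {
  cat(sprintf("vihs_surface: %dx%d cubic B-spline control net over %s quad%s\n",
              nrow(x$ctrl), ncol(x$ctrl), x$anchor$provenance,
              if (x$refined) " (LS-refined)" else " (Coons only)"))
  invisible(x)
}

# evaluate z (and optionally xy-gradient) at parameter pairs (u, v)
vihs_eval_uv <- function(vs, u, v, grad = FALSE) {
  Bu <- bspline_basis(vs$knots, u, vs$degree)
  Bv <- bspline_basis(vs$knots, v, vs$degree)
  z <- rowSums((Bu %*% vs$ctrl) * Bv)
  if (!grad) return(list(z = z))
  dBu <- bspline_basis(vs$knots, u, vs$degree, deriv = 1L)
  dBv <- bspline_basis(vs$knots, v, vs$degree, deriv = 1L)
  zu <- rowSums((dBu %*% vs$ctrl) * Bv)
  zv <- rowSums((Bu %*% vs$ctrl) * dBv)
  J <- bilinear_jac(vs$domain$corners, u, v)
  det <- J$xu * J$yv - J$xv * J$yu
  # [zx, zy] = J^{-T} [zu, zv]
  zx <- (J$yv * zu - J$yu * zv) / det
  zy <- (-J$xv * zu + J$xu * zv) / det
  list(z = z, zx = zx, zy = zy)
}

#' Evaluate the ViHS at physical xy positions
#'
#' Inverts the bilinear parameter map by Newton iteration and evaluates the
#' spline; positions outside the domain quad return `NA`.
#'
#' @param object a `vihs_surface`.
#' @param x,y numeric vectors (mm).
#' @param grad also return the height-field gradient (`zx`, `zy`).
#' @param ... unused.
#' @return data.frame with `z` (and `zx`, `zy` when `grad = TRUE`) and the
#'   logical `inside`.
#' @export
predict.vihs_surface <- function(object, x, y, grad = FALSE, ...) {
  inv <- bilinear_invert(object$domain$corners, x, y)
  inside <- inv$converged & inv$u >= -1e-9 & inv$u <= 1 + 1e-9 &
    inv$v >= -1e-9 & inv$v <= 1 + 1e-9
  out <- data.frame(z = rep(NA_real_, length(x)), inside = inside)
  if (grad) { out$zx <- NA_real_; out$zy <- NA_real_ }
  if (any(inside)) {
    ev <- vihs_eval_uv(object, clamp(inv$u[inside], 0, 1),
                       clamp(inv$v[inside], 0, 1), grad = grad)
    out$z[inside] <- ev$z
    if (grad) { out$zx[inside] <- ev$zx; out$zy[inside] <- ev$zy }
  }
  out
}

#' Evaluate a ViHS on a regular parameter grid and export as colored PLY
#'
#' @param vs a `vihs_surface`.
#' @param path output PLY path.
#' @param n grid resolution per direction.
#' @param binary write binary PLY.
#' @export
write_vihs_ply <- function(vs, path, n = 50L, binary = FALSE) {
  u <- rep(seq(0, 1, length.out = n), n)
  v <- rep(seq(0, 1, length.out = n), each = n)
  xy <- bilinear_xy(vs$domain$corners, u, v)
  z <- vihs_eval_uv(vs, u, v)$z
  hdr <- c("ply", "format ascii 1.0", sprintf("element vertex %d", n * n),
           "property double x", "property double y", "property double z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  writeLines(c(hdr, sprintf("%.9g %.9g %.9g 180 200 230",
                            xy[, 1L], xy[, 2L], z)), path)
  invisible(path)
}

#' Build the full ensemble of ViHS instances
#'
#' One instance anchored to the exact minimal-area rectangle plus `n`
#' instances on scattered quads (defaults give the 31-instance ensemble:
#' 1 initial + 30 scattered). Order is deterministic: initial first, then
#' scatter order. A failing instance is dropped with a warning.
#'
#' @param surface an [organized_surface()].
#' @param wound_mask logical wound mask.
#' @param edge a [wound_edge()].
#' @param n scattered instances (default 30).
#' @param half_width scatter half-width (mm, default 2.5).
#' @param seed master RNG seed.
#' @param ... fit parameters passed to [fit_vihs()].
#' @return List of `vihs_surface` objects (attribute `n_failed` counts drops).
#' @export
build_instances <- function(surface, wound_mask, edge, n = 30L,
                            half_width = 2.5, seed = 1L, ...) {
  rect <- min_area_rect(edge)
  quads <- c(list(rect),
             if (n > 0L) scatter_quads(rect, n = n, half_width = half_width,
                                       seed = seed))
  out <- vector("list", length(quads))
  failed <- 0L
  for (i in seq_along(quads)) {
    out[[i]] <- tryCatch(fit_vihs(surface, wound_mask, quads[[i]], ...),
                         wm_error = function(e) {
                           wm_warn("ViHS instance %d dropped: %s", i,
                                   conditionMessage(e))
                           NULL
                         })
    if (is.null(out[[i]])) failed <- failed + 1L
  }
  out <- out[!vapply(out, is.null, logical(1L))]
  attr(out, "n_failed") <- failed
  out
}
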