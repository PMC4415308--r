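#' Organized colored 3D surface (range grid)
#'
#' Canonical container for a single-view triangulation scan: a regular
#' `rows x cols` lattice where cell `(r, c)` carries one 3D point and one
#' 8-bit RGB color. Physical x increases with the column index, y with the
#' row index, and z points toward the scanner, so healthy skin is the high-z
#' reference and the wound cavity has lower z. Geometry is stored as a height
#' field: per-axis coordinate vectors (mm) plus a z matrix; invalid cells are
#' `NA` in z and `FALSE` in `valid`.
#'
#' @param xcoord numeric vector of column x positions (mm), strictly increasing.
#' @param ycoord numeric vector of row y positions (mm), strictly increasing.
#' @param z numeric matrix `length(ycoord) x length(xcoord)` of heights (mm);
#'   `NA` marks invalid cells.
#' @param rgb integer array `rows x cols x 3`, values in 0..255, or `NULL`
#'   (filled with mid gray).
#' @param pitch_x,pitch_y nominal grid spacing (mm); defaults to the median
#'   coordinate step.
#' @return An object of class `organized_surface` with fields `rows`, `cols`,
#'   `xcoord`, `ycoord`, `z`, `valid`, `rgb`, `pitch_x`, `pitch_y`.
#' @export
organized_surface <- function(xcoord, ycoord, z, rgb = NULL,
                              pitch_x = NULL, pitch_y = NULL) {
  rows <- length(ycoord); cols <- length(xcoord)
  if (rows < 2L || cols < 2L) wm_stop("wm_empty_input", "grid must be at least 2 x 2")
  z <- as.matrix(z)
  if (!all(dim(z) == c(rows, cols)))
    wm_stop("wm_format_error", "z must be %d x %d", rows, cols)
  if (is.null(pitch_x)) pitch_x <- stats::median(diff(xcoord))
  if (is.null(pitch_y)) pitch_y <- stats::median(diff(ycoord))
  if (!(pitch_x > 0 && pitch_y > 0))
    wm_stop("wm_format_error", "grid pitch must be positive")
  valid <- is.finite(z)
  if (!any(valid)) wm_stop("wm_empty_input", "surface has no valid cells")
  if (is.null(rgb)) {
    rgb <- array(128L, dim = c(rows, cols, 3L))
  } else {
    rgb <- array(as.integer(rgb), dim = c(rows, cols, 3L))
  }
  srf <- structure(list(
    rows = rows, cols = cols,
    xcoord = as.numeric(xcoord), ycoord = as.numeric(ycoord),
    z = z, valid = valid, rgb = rgb,
    pitch_x = pitch_x, pitch_y = pitch_y
  ), class = "organized_surface")
  validate_surface(srf)
}

validate_surface <- function(srf) {
  stopifnot(inherits(srf, "organized_surface"))
  dx <- diff(srf$xcoord); dy <- diff(srf$ycoord)
  if (any(dx <= 0) || any(dy <= 0))
    wm_stop("wm_format_error", "grid coordinates must be strictly increasing")
  # median adjacent spacing must agree with declared pitch within 25%
  if (abs(stats::median(dx) - srf$pitch_x) > 0.25 * srf$pitch_x ||
      abs(stats::median(dy) - srf$pitch_y) > 0.25 * srf$pitch_y)
    wm_stop("wm_format_error", "grid spacing disagrees with declared pitch by >25%%")
  if (any(!is.finite(srf$z[srf$valid])))
    wm_stop("wm_format_error", "valid cells must carry finite z")
  srf
}

#' @export
print.organized_surface <- function(x, ...) {
  cat(sprintf("organized_surface: %d x %d cells, pitch %.3g x %.3g mm\n",
              x$rows, x$cols, x$pitch_x, x$pitch_y))
  cat(sprintf("  x: [%.2f, %.2f] mm, y: [%.2f, %.2f] mm, z: [%.2f, %.2f] mm\n",
              min(x$xcoord), max(x$xcoord), min(x$ycoord), max(x$ycoord),
              min(x$z, na.rm = TRUE), max(x$z, na.rm = TRUE)))
  cat(sprintf("  valid cells: %d / %d\n", sum(x$valid), x$rows * x$cols))
  invisible(x)
}

#' @export
plot.organized_surface <- function(x, what = c("z", "color"), ...) {
  what <- match.arg(what)
  if (what == "z") {
    graphics::image(x$xcoord, x$ycoord, t(x$z), asp = 1,
                    xlab = "x [mm]", ylab = "y [mm]",
                    col = grDevices::hcl.colors(64, "viridis"), ...)
  } else {
    cols <- grDevices::rgb(x$rgb[, , 1L], x$rgb[, , 2L], x$rgb[, , 3L],
                           maxColorValue = 255)
    graphics::plot(NA, xlim = range(x$xcoord), ylim = rev(range(x$ycoord)),
                   asp = 1, xlab = "x [mm]", ylab = "y [mm]", ...)
    graphics::rasterImage(matrix(cols, x$rows, x$cols),
                          min(x$xcoord), max(x$ycoord),
                          max(x$xcoord), min(x$ycoord))
  }
  invisible(x)
}

# --- coordinate helpers -----------------------------------------------------

# fractional grid coordinates (row, col) for physical xy; 1-based
surface_rc_at <- function(srf, x, y) {
  r <- 1 + (y - srf$ycoord[1L]) / srf$pitch_y
  c <- 1 + (x - srf$xcoord[1L]) / srf$pitch_x
  # correct for (small) deviations from exactly uniform spacing
  if (length(srf$xcoord) > 1 &&
      (max(abs(srf$xcoord - (srf$xcoord[1L] + (seq_along(srf$xcoord) - 1) * srf$pitch_x))) >
       1e-9 * srf$pitch_x)) {
    c <- stats::approx(srf$xcoord, seq_along(srf$xcoord), xout = x, rule = 2)$y
    r <- stats::approx(srf$ycoord, seq_along(srf$ycoord), xout = y, rule = 2)$y
  }
  cbind(r = r, c = c)
}

# physical xy at fractional (row, col)
surface_xy_at <- function(srf, rc) {
  x <- srf$xcoord[1L] + (rc[, 2L] - 1) * srf$pitch_x
  y <- srf$ycoord[1L] + (rc[, 1L] - 1) * srf$pitch_y
  cbind(x = x, y = y)
}

# vectorized bilinear interpolation of matrix M at fractional (r, c);
# NA outside the grid or when any participating corner is NA
bilerp <- function(M, r, c) {
  nr <- nrow(M); nc <- ncol(M)
  out <- rep(NA_real_, length(r))
  ok <- is.finite(r) & is.finite(c) & r >= 1 & r <= nr & c >= 1 & c <= nc
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  v <- (1 - fr) * (1 - fc) * M[i00] + fr * (1 - fc) * M[i10] +
    (1 - fr) * fc * M[i01] + fr * fc * M[i11]
  out[ok] <- v
  out
}

# bilinear z lookup at physical xy
surface_z_at <- function(srf, x, y) {
  rc <- surface_rc_at(srf, x, y)
  bilerp(srf$z, rc[, 1L], rc[, 2L])
}

# nearest-cell integer indices (clamped); returns n x 2 matrix
surface_cell_at <- function(srf, x, y) {
  rc <- surface_rc_at(srf, x, y)
  cbind(clamp(round(rc[, 1L]), 1L, srf$rows),
        clamp(round(rc[, 2L]), 1L, srf$cols))
}

#' Extract the aligned 2D color image of a surface
#'
#' The per-cell color of the range grid becomes pixel `(r, c)` of a 2D image
#' with identical dimensions, the canvas on which segmentation runs. Invalid
#' cells become black pixels and are flagged.
#'
#' @param surface an [organized_surface()].
#' @return Object of class `color_image`: list with `rows`, `cols`,
#'   `rgb` (`rows x cols x 3` integer, 0..255) and `valid` (logical matrix).
#' @export
extract_color_image <- function(surface) {
  stopifnot(inherits(surface, "organized_surface"))
  rgb <- surface$rgb
  for (k in 1:3) {
    ch <- rgb[, , k]
    ch[!surface$valid] <- 0L
    rgb[, , k] <- ch
  }
  structure(list(rows = surface$rows, cols = surface$cols,
                 rgb = rgb, valid = surface$valid),
            class = "color_image")
}

#' @export
print.color_image <- function(x, ...) {
  cat(sprintf("color_image: %d x %d px (%d flagged invalid)\n",
              x$rows, x$cols, sum(!x$valid)))
  invisible(x)
}

#' Resample scattered colored points onto a regular grid
#'
#' Builds an [organized_surface()] over the xy bounding box of the points at
#' the requested pitch. Each cell takes the inverse-distance-weighted z and
#' color of the neighbors within radius `2 * pitch`; cells with no neighbor
#' are invalid.
#'
#' @param points numeric matrix with columns x, y, z (mm) and optionally
#'   r, g, b (0..255).
#' @param pitch target grid spacing (mm).
#' @return An [organized_surface()].
#' @export
resample_to_grid <- function(points, pitch) {
  points <- as.matrix(points)
  if (nrow(points) < 3L) wm_stop("wm_degenerate_geometry", "need at least 3 points")
  if (!(pitch > 0)) wm_stop("wm_degenerate_geometry", "pitch must be positive")
  xy <- points[, 1:2, drop = FALSE]
  # collinearity: rank of centered xy
  s <- svd(sweep(xy, 2, colMeans(xy)))$d
  if (s[2L] < 1e-9 * max(s[1L], 1))
    wm_stop("wm_degenerate_geometry", "points are collinear or coincident")
  xr <- range(xy[, 1L]); yr <- range(xy[, 2L])
  xcoord <- seq(xr[1L], xr[2L], by = pitch)
  ycoord <- seq(yr[1L], yr[2L], by = pitch)
  rows <- length(ycoord); cols <- length(xcoord)
  has_col <- ncol(points) >= 6L
  n <- nrow(points)
  rad <- 2 * pitch
  # splat each point onto the cells within a 2-cell window, then keep those
  # within the search radius; inverse-distance weights, aggregated per cell
  ci <- round(1 + (xy[, 1L] - xcoord[1L]) / pitch)
  ri <- round(1 + (xy[, 2L] - ycoord[1L]) / pitch)
  offs <- expand.grid(dr = -2:2, dc = -2:2)
  m <- nrow(offs)
  rr <- rep(ri, m) + rep(offs$dr, each = n)
  cc <- rep(ci, m) + rep(offs$dc, each = n)
  pi_ <- rep(seq_len(n), m)
  ok <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
  rr <- rr[ok]; cc <- cc[ok]; pi_ <- pi_[ok]
  d2 <- (xcoord[cc] - xy[pi_, 1L])^2 + (ycoord[rr] - xy[pi_, 2L])^2
  inr <- d2 <= rad^2
  rr <- rr[inr]; cc <- cc[inr]; pi_ <- pi_[inr]
  w <- 1 / (d2[inr] + (1e-12 * pitch)^2)  # Shepard weights, power 2
  key <- (rr - 1L) * cols + cc
  agg <- function(v) rowsum(v, key)
  aw <- agg(w)
  keys <- as.integer(rownames(aw))
  ii <- cbind((keys - 1L) %/% cols + 1L, (keys - 1L) %% cols + 1L)
  z <- matrix(NA_real_, rows, cols)
  # weighted local plane fit per cell (moving least squares with the Shepard
  # weights); falls back to the weighted mean where the fit is degenerate
  dx <- xy[pi_, 1L] - xcoord[cc]; dy <- xy[pi_, 2L] - ycoord[rr]
  zp <- points[pi_, 3L]
  M <- cbind(w, w * dx, w * dy, w * dx * dx, w * dx * dy, w * dy * dy,
             w * zp, w * zp * dx, w * zp * dy)
  S <- rowsum(M, key)
  zfit <- numeric(nrow(S))
  reg <- (1e-6 * pitch)^2
  for (q in seq_len(nrow(S))) {
    A <- matrix(c(S[q, 1L], S[q, 2L], S[q, 3L],
                  S[q, 2L], S[q, 4L] + reg, S[q, 5L],
                  S[q, 3L], S[q, 5L], S[q, 6L] + reg), 3L, 3L)
    b <- S[q, 7:9]
    est <- tryCatch(solve(A, b)[1L], error = function(e) NA_real_)
    zfit[q] <- if (is.finite(est)) est else S[q, 7L] / S[q, 1L]
  }
  z[ii] <- zfit
  rgb <- NULL
  if (has_col) {
    rgb <- array(128L, dim = c(rows, cols, 3L))
    for (k in 1:3) {
      ch <- matrix(128L, rows, cols)
      ch[ii] <- as.integer(round(clamp(
        as.numeric(agg(w * points[pi_, 3L + k])) / as.numeric(aw), 0, 255)))
      rgb[, , k] <- ch
    }
  }
  organized_surface(xcoord, ycoord, z, rgb, pitch_x = pitch, pitch_y = pitch)
}
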