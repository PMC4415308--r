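# Tensor-product B-spline helpers for the ViHS surface. Non-rational
# (all weights 1), open-uniform knots on [0, 1].

open_uniform_knots <- function(n_ctrl, degree = 3L) {
  ord <- degree + 1L
  ninner <- n_ctrl - ord
  if (ninner < 0L) wm_stop("wm_format_error", "need at least degree+1 control points")
  c(rep(0, ord), if (ninner > 0L) seq_len(ninner) / (ninner + 1L), rep(1, ord))
}

# basis matrix (n x n_ctrl) at parameters u in [0, 1]; deriv = 0 or 1
bspline_basis <- function(knots, u, degree = 3L, deriv = 0L) {
  ord <- degree + 1L
  u <- clamp(u, 0, 1)
  # splineDesign rejects x exactly at the right end unless nudged inside
  u[u >= 1] <- 1 - 1e-12
  splines::splineDesign(knots, u, ord = ord,
                        derivs = rep(deriv, length(u)), outer.ok = FALSE)
}

# Greville abscissae (parameter location "owned" by each control point)
greville <- function(knots, degree = 3L) {
  n <- length(knots) - degree - 1L
  vapply(seq_len(n), function(i) mean(knots[(i + 1L):(i + degree)]), numeric(1L))
}

# divided-difference operators on the Greville abscissae: a linear function
# of the parameter has control points linear in the Greville positions, so
# these annihilate affine data exactly (an unscaled difference penalty would
# bias planes near the clamped ends, where the spacing is non-uniform)
div_diff1 <- function(g) {
  n <- length(g)
  D <- matrix(0, n - 1L, n)
  h <- diff(g)
  for (i in seq_len(n - 1L)) D[i, i:(i + 1L)] <- c(-1, 1) / h[i]
  D
}

div_diff2 <- function(g) {
  n <- length(g)
  D <- matrix(0, n - 2L, n)
  h <- diff(g)
  for (i in seq_len(n - 2L)) {
    h1 <- h[i]; h2 <- h[i + 1L]
    D[i, i:(i + 2L)] <- 2 * c(1 / (h1 * (h1 + h2)), -1 / (h1 * h2),
                              1 / (h2 * (h1 + h2)))
  }
  D
}

# fit a 1D cubic B-spline curve z(t), t in [0,1], to samples (t, z) by LS
# with fixed endpoint coefficients (clamped spline => endpoint interpolation)
fit_bspline_curve <- function(t, z, knots, degree = 3L, z0, z1, ridge = 1e-8) {
  B <- bspline_basis(knots, t, degree)
  n <- ncol(B)
  fixed <- c(1L, n)
  free <- setdiff(seq_len(n), fixed)
  rhs <- z - B[, 1L] * z0 - B[, n] * z1
  Bf <- B[, free, drop = FALSE]
  A <- crossprod(Bf) + diag(ridge, length(free))
  # curvature smoothing keeps the curve tame where samples are sparse
  D <- div_diff2(greville(knots, degree))
  mu <- 1e-4
  Df <- D[, free, drop = FALSE]
  A <- A + mu * crossprod(Df)
  b <- crossprod(Bf, rhs) - mu * crossprod(Df, D[, fixed] %*% c(z0, z1))
  coef <- numeric(n)
  coef[fixed] <- c(z0, z1)
  coef[free] <- solve(A, b)
  coef
}

# thin-plate-style penalty matrix on an n_u x n_v control net, acting on
# vec(C) with C stored column-major (u index fastest); built from divided
# differences so that affine control nets carry zero penalty
ctrl_penalty <- function(gu, gv) {
  n_u <- length(gu); n_v <- length(gv)
  D2u <- div_diff2(gu); D2v <- div_diff2(gv)
  D1u <- div_diff1(gu); D1v <- div_diff1(gv)
  Iu <- diag(n_u); Iv <- diag(n_v)
  kronecker(Iv, crossprod(D2u)) +
    2 * kronecker(crossprod(D1v), crossprod(D1u)) +
    kronecker(crossprod(D2v), Iu)
}

# --- bilinear (u,v) -> (x,y) map of a quadrilateral -------------------------

# corners: 4 x 2, CCW, corner 1 = (u,v)=(0,0), 2 = (1,0), 3 = (1,1), 4 = (0,1)
bilinear_xy <- function(corners, u, v) {
  P <- corners
  x <- (1 - u) * (1 - v) * P[1L, 1L] + u * (1 - v) * P[2L, 1L] +
    u * v * P[3L, 1L] + (1 - u) * v * P[4L, 1L]
  y <- (1 - u) * (1 - v) * P[1L, 2L] + u * (1 - v) * P[2L, 2L] +
    u * v * P[3L, 2L] + (1 - u) * v * P[4L, 2L]
  cbind(x = x, y = y)
}

# Jacobian columns dS/du, dS/dv at (u, v); returns list of 4 vectors
bilinear_jac <- function(corners, u, v) {
  P <- corners
  list(
    xu = (1 - v) * (P[2L, 1L] - P[1L, 1L]) + v * (P[3L, 1L] - P[4L, 1L]),
    yu = (1 - v) * (P[2L, 2L] - P[1L, 2L]) + v * (P[3L, 2L] - P[4L, 2L]),
    xv = (1 - u) * (P[4L, 1L] - P[1L, 1L]) + u * (P[3L, 1L] - P[2L, 1L]),
    yv = (1 - u) * (P[4L, 2L] - P[1L, 2L]) + u * (P[3L, 2L] - P[2L, 2L]))
}

# vectorized Newton inversion of the bilinear map; returns (u, v) and a
# convergence flag. Points far outside the quad are flagged non-converged.
bilinear_invert <- function(corners, x, y, tol = 1e-9, max_iter = 25L) {
  n <- length(x)
  # affine initialization from corners 1-2-4
  e1 <- corners[2L, ] - corners[1L, ]; e2 <- corners[4L, ] - corners[1L, ]
  det0 <- e1[1L] * e2[2L] - e1[2L] * e2[1L]
  dx <- x - corners[1L, 1L]; dy <- y - corners[1L, 2L]
  u <- (dx * e2[2L] - dy * e2[1L]) / det0
  v <- (-dx * e1[2L] + dy * e1[1L]) / det0
  conv <- rep(FALSE, n)
  for (it in seq_len(max_iter)) {
    S <- bilinear_xy(corners, u, v)
    fx <- S[, 1L] - x; fy <- S[, 2L] - y
    res <- abs(fx) + abs(fy)
    conv <- res < tol
    if (all(conv)) break
    J <- bilinear_jac(corners, u, v)
    det <- J$xu * J$yv - J$xv * J$yu
    det[abs(det) < 1e-300] <- 1e-300
    du <- (fx * J$yv - fy * J$xv) / det
    dv <- (-fx * J$yu + fy * J$xu) / det
    u <- u - du; v <- v - dv
    # keep iterates from wandering off for far-outside points
    u <- clamp(u, -1, 2); v <- clamp(v, -1, 2)
  }
  list(u = u, v = v, converged = conv)
}
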