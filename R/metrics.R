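# Wound metrology: signed deviation field between measured surface and ViHS,
# VDW integration, perimeter and area on the ViHS, ensemble aggregation.

#' Signed deviation field between measured surface and a ViHS instance
#'
#' A regular xy grid at step `h` on the global lattice (coordinates are
#' multiples of `h`, so all instances of one analysis share cell positions)
#' covering the ViHS domain quad. Per cell: the signed deviation
#' `d = z_measured - z_vihs` (measured z by bilinear interpolation of the
#' range grid, ViHS z by Newton inversion of the parameter map), the ViHS
#' area element `h^2 * sqrt(1 + zx^2 + zy^2)`, and the in-wound flag
#' (point-in-polygon against the wound edge, or a precomputed raster).
#'
#' @param surface an [organized_surface()].
#' @param vihs a `vihs_surface`.
#' @param edge a [wound_edge()]; its xy polygon defines the wound region.
#' @param h integration step (mm, default 0.25).
#' @param wound_raster optional raster from [rasterize_wound()] (computed
#'   internally when missing).
#' @return Object of class `deviation_field`.
#' @export
deviation_field <- function(surface, vihs, edge, h = 0.25,
                            wound_raster = NULL) {
  stopifnot(inherits(vihs, "vihs_surface"), h > 0)
  P <- vihs$domain$corners
  xg <- seq(floor(min(P[, 1L]) / h), ceiling(max(P[, 1L]) / h)) * h
  yg <- seq(floor(min(P[, 2L]) / h), ceiling(max(P[, 2L]) / h)) * h
  nx <- length(xg); ny <- length(yg)
  xx <- rep(xg, each = ny); yy <- rep(yg, nx)
  inv <- bilinear_invert(P, xx, yy)
  inside <- inv$converged & inv$u >= 0 & inv$u <= 1 & inv$v >= 0 & inv$v <= 1
  n_bad <- sum(!inv$converged & inv$u > 0 & inv$u < 1 & inv$v > 0 & inv$v < 1)
  if (n_bad > 0.01 * max(1L, sum(inside)))
    wm_stop("wm_field_degenerate",
            "parameter inversion diverged at >1%% of interior cells")
  d <- matrix(NA_real_, ny, nx)
  ae <- matrix(NA_real_, ny, nx)
  if (any(inside)) {
    ev <- vihs_eval_uv(vihs, inv$u[inside], inv$v[inside], grad = TRUE)
    zmeas <- surface_z_at(surface, xx[inside], yy[inside])
    d[inside] <- zmeas - ev$z
    ae[inside] <- h^2 * sqrt(1 + ev$zx^2 + ev$zy^2)
  }
  if (is.null(wound_raster)) wound_raster <- rasterize_wound(edge, h)
  iw <- matrix(FALSE, ny, nx)
  iw[] <- wound_raster_lookup(wound_raster, xx, yy)
  clipped <- sum(iw & !inside)
  if (clipped > 0)
    wm_warn("%d in-wound cells fall outside the ViHS domain (clipped)", clipped)
  iw <- iw & inside
  structure(list(xg = xg, yg = yg, h = h, d = d, area_el = ae,
                 in_wound = iw, in_domain = matrix(inside, ny, nx)),
            class = "deviation_field")
}

#' Rasterize the wound edge polygon on the global lattice at step h
#'
#' @param edge a [wound_edge()].
#' @param h lattice step (mm).
#' @return Lookup object used by [deviation_field()].
#' @export
rasterize_wound <- function(edge, h) {
  xy <- edge$xy
  xr <- range(xy[, 1L]); yr <- range(xy[, 2L])
  xi0 <- floor(xr[1L] / h) - 1L; xi1 <- ceiling(xr[2L] / h) + 1L
  yi0 <- floor(yr[1L] / h) - 1L; yi1 <- ceiling(yr[2L] / h) + 1L
  xg <- (xi0:xi1) * h; yg <- (yi0:yi1) * h
  px <- rep(xg, each = length(yg)); py <- rep(yg, length(xg))
  m <- matrix(point_in_polygon(px, py, xy), length(yg), length(xg))
  list(xi0 = xi0, yi0 = yi0, h = h, m = m)
}

wound_raster_lookup <- function(wr, x, y) {
  ci <- as.integer(round(x / wr$h)) - wr$xi0 + 1L
  ri <- as.integer(round(y / wr$h)) - wr$yi0 + 1L
  ok <- ri >= 1L & ri <= nrow(wr$m) & ci >= 1L & ci <= ncol(wr$m)
  out <- logical(length(x))
  out[ok] <- wr$m[cbind(ri[ok], ci[ok])]
  out
}

#' Integrate the volumetric deviation of the wound (VDW)
#'
#' Over in-wound cells only: `v_pos = sum(max(d, 0)) * h^2` (tissue above the
#' ViHS), `v_neg = sum(min(d, 0)) * h^2` (cavity below it), and
#' `vdw = v_pos + |v_neg|`. Summing absolute values keeps equal positive and
#' negative volumes from cancelling to a misleading zero.
#'
#' @param field a [deviation_field()].
#' @return List with `v_pos` (mm^3, >= 0), `v_neg` (mm^3, <= 0), `vdw`.
#' @export
integrate_vdw <- function(field) {
  stopifnot(inherits(field, "deviation_field"))
  d <- field$d[field$in_wound]
  if (!length(d)) wm_stop("wm_empty_wound", "no in-wound cells in the field")
  d[!is.finite(d)] <- 0
  v_pos <- sum(pmax(d, 0)) * field$h^2
  v_neg <- sum(pmin(d, 0)) * field$h^2
  list(v_pos = v_pos, v_neg = v_neg, vdw = v_pos + abs(v_neg))
}

#' Perimeter and area of the wound on the ViHS
#'
#' The wound edge is densified to at most `h` spacing, lifted onto the ViHS
#' (each xy vertex given the ViHS height), and its closed 3D polyline length
#' is the perimeter. The area is the sum of ViHS area elements over in-wound
#' cells. Both therefore depend on the ViHS instance, which is what makes
#' averaging them over the scattered ensemble meaningful.
#'
#' @param vihs a `vihs_surface`.
#' @param edge a [wound_edge()].
#' @param field the matching [deviation_field()].
#' @param frame `"vihs"` (default) or `"measured"`: lift the edge and take
#'   area elements on the ViHS, or on the measured surface instead.
#' @param surface required when `frame = "measured"`.
#' @return List with `perimeter` (mm) and `area` (mm^2).
#' @export
measure_perimeter_area <- function(vihs, edge, field, frame = c("vihs", "measured"),
                                   surface = NULL) {
  frame <- match.arg(frame)
  dens <- densify_closed(edge$xy, field$h)
  if (frame == "vihs") {
    pz <- predict(vihs, dens[, 1L], dens[, 2L])$z
    area <- sum(field$area_el[field$in_wound])
  } else {
    stopifnot(!is.null(surface))
    pz <- surface_z_at(surface, dens[, 1L], dens[, 2L])
    # measured-surface area elements by central differences at field cells
    iw <- which(field$in_wound, arr.ind = TRUE)
    x <- field$xg[iw[, 2L]]; y <- field$yg[iw[, 1L]]
    hh <- field$h
    zx <- (surface_z_at(surface, x + hh, y) - surface_z_at(surface, x - hh, y)) / (2 * hh)
    zy <- (surface_z_at(surface, x, y + hh) - surface_z_at(surface, x, y - hh)) / (2 * hh)
    zx[!is.finite(zx)] <- 0; zy[!is.finite(zy)] <- 0
    area <- sum(hh^2 * sqrt(1 + zx^2 + zy^2))
  }
  # close small NA runs (vertices marginally outside the domain)
  if (anyNA(pz)) {
    idx <- seq_along(pz)
    pz <- stats::approx(idx[!is.na(pz)], pz[!is.na(pz)], xout = idx,
                        rule = 2)$y
  }
  p3 <- cbind(dens, pz)
  list(perimeter = polyline_length(p3, closed = TRUE), area = area)
}

#' Full wound analysis: ensemble of ViHS instances and averaged metrics
#'
#' Runs the complete measurement on a segmented wound: anchor rectangle,
#' scattered quads, one ViHS fit per quad, and per instance the deviation
#' field, VDW integration and perimeter/area. The reported result is the
#' mean (and sample standard deviation) over the surviving instances.
#'
#' When `wound` is a mask, its traced contour is smoothed and offset outward
#' by half the grid pitch before measurement (see [smooth_edge()]); a
#' [wound_edge()] passed directly is used as-is.
#'
#' @param surface an [organized_surface()].
#' @param wound a logical wound mask or a [wound_edge()].
#' @param config a [wound_config()] list (individual elements can be
#'   overridden via `...`).
#' @param ... config overrides, e.g. `scatter = list(n = 0)`.
#' @return Object of class `wound_analysis`: `instances` data frame
#'   (perimeter, area, v_pos, v_neg, vdw), `summary`, `config`, `warnings`.
#' @export
analyze <- function(surface, wound, config = wound_config(), ...) {
  config <- utils::modifyList(config, list(...))
  stopifnot(inherits(surface, "organized_surface"))
  warnings <- character()
  if (inherits(wound, "wound_edge")) {
    edge <- wound
    mask <- edge_to_mask(edge_with_rc(wound, surface), surface$rows, surface$cols)
  } else {
    mask <- clean_mask(as.matrix(wound) > 0)
    raw_edge <- mask_to_edge(mask, surface)
    edge <- smooth_edge(raw_edge,
                        sigma = config$edge$smooth_sigma_px,
                        offset = if (identical(config$edge$offset, "auto"))
                          min(surface$pitch_x, surface$pitch_y) / 2
                        else config$edge$offset,
                        resample_to = config$edge$resample_to)
  }
  insts <- build_instances(surface, mask, edge,
                           n = config$scatter$n,
                           half_width = config$scatter$half_width_mm,
                           seed = config$seed,
                           n_ctrl = config$vihs$n_ctrl,
                           degree = config$vihs$degree,
                           lambda = config$vihs$lambda,
                           margin_mm = config$vihs$margin_mm,
                           min_samples = config$vihs$min_samples)
  n_failed <- attr(insts, "n_failed") %||% 0L
  n_target <- config$scatter$n + 1L
  if (length(insts) < ceiling(n_target / 2))
    wm_stop("wm_analysis_failed", ">=50%% of ViHS instances failed")
  if (n_failed > 0L)
    warnings <- c(warnings, sprintf("%d ViHS instance(s) dropped", n_failed))
  h <- config$integration$h
  wr <- rasterize_wound(edge, h)
  rows <- lapply(insts, function(vs) {
    fld <- deviation_field(surface, vs, edge, h = h, wound_raster = wr)
    vv <- integrate_vdw(fld)
    pa <- measure_perimeter_area(vs, edge, fld, frame = config$frame,
                                 surface = surface)
    data.frame(perimeter = pa$perimeter, area = pa$area,
               v_pos = vv$v_pos, v_neg = vv$v_neg, vdw = vv$vdw)
  })
  instances <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("perimeter", "area", "vdw"),
    mean = c(mean(instances$perimeter), mean(instances$area),
             mean(instances$vdw)),
    sd = c(stats::sd(instances$perimeter), stats::sd(instances$area),
           stats::sd(instances$vdw)))
  structure(list(instances = instances, summary = summ,
                 n_instances = nrow(instances), n_failed = n_failed,
                 edge = edge, config = config, seed = config$seed,
                 warnings = warnings),
            class = "wound_analysis")
}

# ensure an edge carries grid coordinates for rasterization
edge_with_rc <- function(edge, surface) {
  if (!is.null(edge$rc)) return(edge)
  rc <- surface_rc_at(surface, edge$xy[, 1L], edge$xy[, 2L])
  wound_edge(edge$xy, rc)
}

#' @export
print.wound_analysis <- function(x, ...) {
  cat(sprintf("wound_analysis: %d ViHS instances (%d dropped)\n",
              x$n_instances, x$n_failed))
  s <- x$summary
  cat(sprintf("  perimeter: %8.2f mm    (sd %.3f)\n", s$mean[1L], s$sd[1L]))
  cat(sprintf("  area:      %8.2f mm^2  (sd %.3f)\n", s$mean[2L], s$sd[2L]))
  cat(sprintf("  VDW:       %8.2f mm^3  (sd %.3f)\n", s$mean[3L], s$sd[3L]))
  invisible(x)
}

#' @export
summary.wound_analysis <- function(object, ...) {
  cat("Wound measurement (ensemble of", object$n_instances, "ViHS instances)\n\n")
  print(object$summary, row.names = FALSE)
  cat("\nPer-instance spread:\n")
  print(summary(object$instances[, c("perimeter", "area", "vdw")]))
  invisible(object$summary)
}

#' @export
plot.wound_analysis <- function(x, ...) {
  graphics::par(mfrow = c(1, 3))
  on.exit(graphics::par(mfrow = c(1, 1)))
  for (m in c("perimeter", "area", "vdw")) {
    graphics::hist(x$instances[[m]], main = m,
                   xlab = switch(m, perimeter = "mm", area = "mm^2", "mm^3"),
                   col = "grey80", border = "white", ...)
    graphics::abline(v = mean(x$instances[[m]]), col = 2, lwd = 2)
  }
  invisible(x)
}

#' Repeatability reporting: per-group spread, Levene and Kruskal-Wallis tests
#'
#' Summarizes repeated measurements grouped by operator/method/run: the
#' per-group standard deviation, Levene's test of variance homogeneity and
#' the one-way Kruskal-Wallis test of location, at the conventional 95%
#' confidence level.
#'
#' @param groups list (>= 2) of numeric vectors (each >= 2 values).
#' @return List with `group_sd`, `levene_p`, `kruskal_p`, `conf_level`.
#' @export
repeatability_stats <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L ||
      any(vapply(groups, length, integer(1L)) < 2L))
    wm_stop("wm_stats_insufficient", "need >= 2 groups of >= 2 values")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  if (stats::var(y) < .Machine$double.eps) {
    # degenerate all-constant data: no evidence against either hypothesis
    return(list(group_sd = vapply(groups, stats::sd, numeric(1L)),
                levene_p = 1, kruskal_p = 1, conf_level = 0.95))
  }
  lev <- car::leveneTest(y, g, center = mean)
  kw <- stats::kruskal.test(y, g)
  kw_p <- kw$p.value
  if (is.nan(kw_p)) kw_p <- 1  # all-tied ranks
  list(group_sd = vapply(groups, stats::sd, numeric(1L)),
       levene_p = lev[["Pr(>F)"]][1L],
       kruskal_p = kw_p,
       conf_level = 0.95)
}
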