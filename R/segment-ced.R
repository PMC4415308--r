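# Canny-edge-detector (CED) wound segmentation: channel selection, hysteresis
# edge detection, automatic/manual edge closing, interior fill.

color_channel <- function(image, channel = c("R", "G", "B", "gray", "hue", "sat")) {
  channel <- match.arg(channel)
  r <- image$rgb[, , 1L] / 255; g <- image$rgb[, , 2L] / 255
  b <- image$rgb[, , 3L] / 255
  switch(channel,
    R = r, G = g, B = b,
    gray = 0.299 * r + 0.587 * g + 0.114 * b,
    hue = {
      mx <- pmax(r, g, b); mn <- pmin(r, g, b); d <- mx - mn
      h <- matrix(0, nrow(r), ncol(r))
      i <- d > 0 & mx == r; h[i] <- ((g - b) / d)[i] %% 6
      i <- d > 0 & mx == g; h[i] <- ((b - r) / d + 2)[i]
      i <- d > 0 & mx == b; h[i] <- ((r - g) / d + 4)[i]
      h / 6
    },
    sat = {
      mx <- pmax(r, g, b); mn <- pmin(r, g, b)
      s <- matrix(0, nrow(r), ncol(r))
      i <- mx > 0; s[i] <- ((mx - mn) / mx)[i]
      s
    })
}

shift_mat <- function(M, dr, dc, fill = 0) {
  nr <- nrow(M); nc <- ncol(M)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- M[rs - dr, cs - dc]
  out
}

# Canny edge map: Gaussian smoothing, Sobel gradient, non-maximum suppression,
# hysteresis thresholding (thresholds relative to the max gradient magnitude)
canny_edges <- function(ch, t_low, t_high, sigma = 1.4) {
  if (sigma > 0)
    ch <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(ch)),
                                              sigma = sigma)))
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  conv3 <- function(M, k) {
    out <- matrix(0, nrow(M), ncol(M))
    for (i in 1:3) for (j in 1:3)
      if (k[i, j] != 0) out <- out + k[i, j] * shift_mat(M, 2L - i, 2L - j)
    out
  }
  gx <- conv3(ch, kx)     # d/dx: differences across columns
  gy <- conv3(ch, t(kx))  # d/dy: differences across rows
  mag <- sqrt(gx^2 + gy^2)
  # zero out the border band: shift padding makes spurious gradients there
  bw <- max(2L, ceiling(sigma))
  mag[c(seq_len(bw), nrow(mag) - seq_len(bw) + 1L), ] <- 0
  mag[, c(seq_len(bw), ncol(mag) - seq_len(bw) + 1L)] <- 0
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(ch), ncol(ch)))
  ang <- atan2(gy, gx)  # gradient direction
  sector <- (round(ang / (pi / 4)) %% 4)
  # neighbors along the gradient for each sector: 0 = horizontal gradient
  n1 <- matrix(0, nrow(ch), ncol(ch)); n2 <- n1
  pick <- function(s, dr, dc) {
    i <- sector == s
    n1[i] <<- shift_mat(mag, dr, dc)[i]
    n2[i] <<- shift_mat(mag, -dr, -dc)[i]
  }
  pick(0, 0L, 1L); pick(1, 1L, 1L); pick(2, 1L, 0L); pick(3, 1L, -1L)
  nms <- mag >= n1 & mag >= n2
  strong <- nms & mag >= t_high * mx
  weak <- nms & mag >= t_low * mx
  hysteresis_link(strong, weak)
}

# keep weak-edge components (8-connected) that contain a strong pixel
hysteresis_link <- function(strong, weak) {
  if (!any(weak)) return(strong)
  idx <- which(weak)
  nr <- nrow(weak)
  # 8-connectivity graph over weak pixels via igraph components
  pos <- which(weak, arr.ind = TRUE)
  id <- matrix(0L, nr, ncol(weak))
  id[idx] <- seq_along(idx)
  elist <- list()
  shifts <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
  for (k in seq_len(nrow(shifts))) {
    nb <- shift_mat(id, shifts[k, 1L], shifts[k, 2L])
    both <- id > 0 & nb > 0
    if (any(both)) elist[[k]] <- cbind(id[both], nb[both])
  }
  el <- do.call(rbind, elist)
  memb <- if (is.null(el)) seq_along(idx) else {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
    igraph::components(g)$membership
  }
  keep <- unique(memb[id[strong & weak]])
  out <- matrix(FALSE, nr, ncol(weak))
  out[idx[memb %in% keep]] <- TRUE
  out | strong
}

# rasterize polylines (list of n x 2 (row, col) matrices) onto a logical canvas
rasterize_strokes <- function(strokes, rows, cols, width = 1L) {
  out <- matrix(FALSE, rows, cols)
  for (p in strokes) {
    p <- as.matrix(p)
    if (nrow(p) < 2L) next
    for (i in seq_len(nrow(p) - 1L)) {
      a <- p[i, ]; b <- p[i + 1L, ]
      k <- max(2L, ceiling(max(abs(b - a))) * 2L)
      t <- seq(0, 1, length.out = k)
      rr <- round(a[1L] + t * (b[1L] - a[1L]))
      cc <- round(a[2L] + t * (b[2L] - a[2L]))
      ok <- rr >= 1 & rr <= rows & cc >= 1 & cc <= cols
      out[cbind(rr[ok], cc[ok])] <- TRUE
    }
  }
  if (width > 1L)
    out <- t(EBImage::imageData(EBImage::dilate(
      EBImage::Image(t(out * 1)), EBImage::makeBrush(2L * (width %/% 2L) + 1L,
                                                     "disc")))) > 0
  out
}

# bridge residual gaps: connect free endpoints of the edge map that are
# within gap_max pixels of each other by straight segments
bridge_gaps <- function(edges, gap_max) {
  if (gap_max <= 0) return(edges)
  nbcount <- matrix(0, nrow(edges), ncol(edges))
  for (dr in -1:1) for (dc in -1:1)
    if (dr != 0 || dc != 0) nbcount <- nbcount + shift_mat(edges * 1, dr, dc)
  ends <- which(edges & nbcount <= 1L, arr.ind = TRUE)
  if (nrow(ends) < 2L) return(edges)
  for (i in seq_len(nrow(ends) - 1L)) {
    d <- sqrt((ends[-(1:i), 1L, drop = FALSE] - ends[i, 1L])^2 +
                (ends[-(1:i), 2L, drop = FALSE] - ends[i, 2L])^2)
    j <- which(d <= gap_max & d > 1.5)
    if (length(j)) {
      j <- i + j[which.min(d[j])]
      edges <- edges | rasterize_strokes(list(rbind(ends[i, ], ends[j, ])),
                                         nrow(edges), ncol(edges))
    }
  }
  edges
}

#' Wound segmentation via the Canny edge pipeline
#'
#' Operator workflow mirrored non-interactively: pick the color channel where
#' the wound edge is most visible, run the Canny detector with hysteresis
#' thresholds, close the edge automatically (morphological closing, then
#' straight-segment bridging of residual small gaps) and/or with manual
#' strokes, and fill the enclosed interior. The largest enclosed region is
#' the wound mask.
#'
#' @param image a `color_image` from [extract_color_image()].
#' @param channel color channel: `"R"`, `"G"`, `"B"`, `"gray"`, `"hue"`,
#'   `"sat"`.
#' @param t_low,t_high hysteresis thresholds as fractions of the maximum
#'   gradient magnitude, `t_low <= t_high`.
#' @param close_radius disc radius (px) of the morphological closing.
#' @param manual_strokes optional list of polylines (n x 2 (row, col)
#'   matrices) drawn by the operator to close the edge.
#' @param sigma Gaussian pre-smoothing bandwidth (px).
#' @param gap_max maximal gap (px) bridged by straight segments.
#' @return Logical wound mask (largest enclosed component).
#' @export
segment_ced <- function(image, channel = "G", t_low = 0.1, t_high = 0.3,
                        close_radius = 3L, manual_strokes = NULL,
                        sigma = 1.4, gap_max = 10) {
  stopifnot(inherits(image, "color_image"))
  if (t_low > t_high) wm_stop("wm_format_error", "t_low must be <= t_high")
  if (image$rows * image$cols == 0L) wm_stop("wm_empty_input", "empty image")
  ch <- color_channel(image, channel)
  edges <- canny_edges(ch, t_low, t_high, sigma)
  if (close_radius > 0) {
    br <- EBImage::makeBrush(2L * as.integer(close_radius) + 1L, "disc")
    edges <- t(EBImage::imageData(EBImage::closing(
      EBImage::Image(t(edges * 1)), br))) > 0
  }
  if (!is.null(manual_strokes))
    edges <- edges | rasterize_strokes(manual_strokes, image$rows, image$cols,
                                       width = 3L)
  edges <- bridge_gaps(edges, gap_max)
  interior_fill(edges, image)
}

# regions not reachable from the image border across the edge map
interior_fill <- function(edges, image) {
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t((!edges) * 1)))))
  border_labels <- unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L],
                            lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  interior <- lab > 0 & !(lab %in% border_labels)
  if (!any(interior))
    wm_stop("wm_edge_not_closed",
            "no closed region found; add strokes or raise close_radius")
  interior <- largest_component(interior)
  # annex the edge pixels adjacent to the chosen interior (the contour itself)
  grow <- t(EBImage::imageData(EBImage::dilate(
    EBImage::Image(t(interior * 1)), EBImage::makeBrush(3L, "box")))) > 0
  mask <- interior | (edges & grow)
  mask <- fill_holes(largest_component(mask)) & image$valid
  if (!any(mask)) wm_stop("wm_edge_not_closed", "enclosed region entirely invalid")
  mask
}
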