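# Surface file I/O: colored PLY (ascii / binary little-endian) and the
# depth_pair format (16-bit grayscale TIFF depth + 8-bit PNG color + JSON
# sidecar with the physical scale).

#' Read a colored 3D surface
#'
#' @param path file path. For `format = "ply"` a PLY file with per-vertex
#'   uchar red/green/blue; for `format = "depth_pair"` the path of the JSON
#'   sidecar written by [write_surface()] (which names the depth and color
#'   PNGs).
#' @param format `"ply"` or `"depth_pair"`.
#' @param pitch grid pitch (mm) used when an unorganized PLY must be resampled
#'   onto a regular grid; default estimates it from point density.
#' @return An [organized_surface()].
#' @export
read_surface <- function(path, format = c("ply", "depth_pair"), pitch = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) wm_stop("wm_format_error", "file not found: %s", path)
  if (format == "ply") read_surface_ply(path, pitch) else read_surface_depth(path)
}

#' Write a colored 3D surface
#'
#' @param surface an [organized_surface()].
#' @param path output path (PLY file, or JSON sidecar path for `depth_pair`).
#' @param format `"ply"` or `"depth_pair"`.
#' @param binary write binary-little-endian PLY instead of ascii.
#' @return `path`, invisibly.
#' @export
write_surface <- function(surface, path, format = c("ply", "depth_pair"),
                          binary = FALSE) {
  format <- match.arg(format)
  stopifnot(inherits(surface, "organized_surface"))
  if (format == "ply") write_surface_ply(surface, path, binary)
  else write_surface_depth(surface, path)
  invisible(path)
}

# --- PLY --------------------------------------------------------------------

parse_ply_header <- function(con) {
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "ply")) wm_stop("wm_format_error", "not a PLY file")
  fmt <- NULL; nvert <- NULL; props <- character(); ptype <- character()
  in_vertex <- FALSE
  repeat {
    ln <- readLines(con, n = 1L)
    if (length(ln) == 0L) wm_stop("wm_format_error", "truncated PLY header")
    tok <- strsplit(trimws(ln), "\\s+")[[1L]]
    if (tok[1L] == "format") fmt <- tok[2L]
    else if (tok[1L] == "element") {
      in_vertex <- tok[2L] == "vertex"
      if (in_vertex) nvert <- as.integer(tok[3L])
    } else if (tok[1L] == "property" && in_vertex) {
      props <- c(props, tok[3L]); ptype <- c(ptype, tok[2L])
    } else if (tok[1L] == "end_header") break
  }
  if (is.null(nvert)) wm_stop("wm_format_error", "PLY has no vertex element")
  list(format = fmt, nvert = nvert, props = props, ptype = ptype)
}

ply_type_size <- function(t) {
  switch(t,
    char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
    double = 8L, float64 = 8L,
    wm_stop("wm_format_error", "unsupported PLY property type: %s", t))
}

read_ply_points <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  need <- c("x", "y", "z")
  if (!all(need %in% hdr$props))
    wm_stop("wm_format_error", "PLY lacks x/y/z vertex properties")
  has_col <- all(c("red", "green", "blue") %in% hdr$props)
  if (!has_col) wm_stop("wm_color_missing", "PLY has no per-vertex color")
  if (hdr$nvert == 0L) wm_stop("wm_empty_input", "PLY has no vertices")
  np <- length(hdr$props)
  if (identical(hdr$format, "ascii")) {
    dat <- tryCatch(
      matrix(scan(con, what = numeric(), n = hdr$nvert * np, quiet = TRUE),
             ncol = np, byrow = TRUE),
      error = function(e) wm_stop("wm_format_error", "truncated PLY data"))
    if (nrow(dat) < hdr$nvert) wm_stop("wm_format_error", "truncated PLY data")
  } else if (identical(hdr$format, "binary_little_endian")) {
    sizes <- vapply(hdr$ptype, ply_type_size, integer(1L))
    stride <- sum(sizes)
    raw <- readBin(con, "raw", n = hdr$nvert * stride)
    if (length(raw) < hdr$nvert * stride)
      wm_stop("wm_format_error", "truncated PLY data")
    rm <- matrix(raw, nrow = stride)  # column j = vertex j
    off <- cumsum(c(0L, sizes))
    dat <- matrix(NA_real_, hdr$nvert, np)
    for (j in seq_len(np)) {
      b <- rm[(off[j] + 1L):(off[j] + sizes[j]), , drop = FALSE]
      t <- hdr$ptype[j]
      dat[, j] <- switch(t,
        float = , float32 = readBin(as.vector(b), "double", n = hdr$nvert,
                                    size = 4L, endian = "little"),
        double = , float64 = readBin(as.vector(b), "double", n = hdr$nvert,
                                     size = 8L, endian = "little"),
        uchar = , uint8 = as.numeric(as.integer(as.vector(b))),
        char = , int8 = readBin(as.vector(b), "integer", n = hdr$nvert,
                                size = 1L, signed = TRUE, endian = "little"),
        readBin(as.vector(b), "integer", n = hdr$nvert, size = sizes[j],
                endian = "little"))
    }
  } else {
    wm_stop("wm_format_error", "unsupported PLY format: %s", hdr$format)
  }
  colnames(dat) <- hdr$props
  dat[, c("x", "y", "z", "red", "green", "blue"), drop = FALSE]
}

read_surface_ply <- function(path, pitch = NULL) {
  pts <- read_ply_points(path)
  # if the points already form a complete regular grid, reconstruct it exactly
  ux <- sort(unique(pts[, "x"])); uy <- sort(unique(pts[, "y"]))
  if (length(ux) * length(uy) == nrow(pts) &&
      length(ux) > 1L && length(uy) > 1L &&
      diff(range(diff(ux))) < 1e-6 * stats::median(diff(ux)) &&
      diff(range(diff(uy))) < 1e-6 * stats::median(diff(uy))) {
    ci <- match(pts[, "x"], ux); ri <- match(pts[, "y"], uy)
    z <- matrix(NA_real_, length(uy), length(ux))
    z[cbind(ri, ci)] <- pts[, "z"]
    rgb <- array(128L, dim = c(length(uy), length(ux), 3L))
    for (k in 1:3) {
      ch <- matrix(0L, length(uy), length(ux))
      ch[cbind(ri, ci)] <- as.integer(pts[, 3L + k])
      rgb[, , k] <- ch
    }
    return(organized_surface(ux, uy, z, rgb))
  }
  if (is.null(pitch)) {
    area <- diff(range(pts[, "x"])) * diff(range(pts[, "y"]))
    pitch <- sqrt(area / nrow(pts))
  }
  resample_to_grid(pts, pitch)
}

write_surface_ply <- function(srf, path, binary = FALSE) {
  v <- which(srf$valid, arr.ind = TRUE)
  x <- srf$xcoord[v[, 2L]]; y <- srf$ycoord[v[, 1L]]; z <- srf$z[v]
  r <- srf$rgb[, , 1L][v]; g <- srf$rgb[, , 2L][v]; b <- srf$rgb[, , 3L][v]
  n <- length(x)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", n),
           "property double x", "property double y", "property double z",
           "property uchar red", "property uchar green", "property uchar blue",
           "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(c(x[i], y[i], z[i]), con, size = 8L, endian = "little")
      writeBin(as.raw(c(r[i], g[i], b[i])), con)
    }
  } else {
    writeLines(sprintf("%.9g %.9g %.9g %d %d %d", x, y, z, r, g, b), con)
  }
  invisible(path)
}

# --- depth_pair -------------------------------------------------------------

# 16-bit depth image: code 0 = invalid sentinel,
# z = (code - 1) * z_scale + z_offset

write_surface_depth <- function(srf, sidecar_path) {
  base <- sub("\\.json$", "", sidecar_path)
  depth_path <- paste0(base, "_depth.tif")
  color_path <- paste0(base, "_color.png")
  zr <- range(srf$z, na.rm = TRUE)
  z_offset <- zr[1L]
  z_scale <- max((zr[2L] - zr[1L]), 1e-9) / 65533
  code <- matrix(0, srf$rows, srf$cols)
  code[srf$valid] <- round((srf$z[srf$valid] - z_offset) / z_scale) + 1
  tiff::writeTIFF(code / 65535, depth_path, bits.per.sample = 16L)
  col <- array(0, dim = c(srf$cols, srf$rows, 3L))
  for (k in 1:3) col[, , k] <- t(srf$rgb[, , k]) / 255
  EBImage::writeImage(EBImage::Image(col, colormode = "Color"), color_path,
                      type = "png", bits = 8L)
  meta <- list(rows = srf$rows, cols = srf$cols,
               pitch_mm = c(x = srf$pitch_x, y = srf$pitch_y),
               origin_mm = c(x = srf$xcoord[1L], y = srf$ycoord[1L]),
               z_scale = z_scale, z_offset = z_offset,
               depth = basename(depth_path), color = basename(color_path))
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sidecar_path)
}

read_surface_depth <- function(sidecar_path) {
  meta <- tryCatch(jsonlite::read_json(sidecar_path, simplifyVector = TRUE),
                   error = function(e)
                     wm_stop("wm_format_error", "unreadable sidecar: %s",
                             sidecar_path))
  for (f in c("pitch_mm", "z_scale", "z_offset", "depth", "color"))
    if (is.null(meta[[f]]))
      wm_stop("wm_format_error", "sidecar lacks field '%s'", f)
  dir <- dirname(sidecar_path)
  dimg <- tiff::readTIFF(file.path(dir, meta$depth))
  cimg <- EBImage::readImage(file.path(dir, meta$color))
  code <- round(dimg * 65535)
  z <- (code - 1) * meta$z_scale + meta$z_offset
  z[code == 0] <- NA_real_
  rows <- nrow(z); cols <- ncol(z)
  cd <- EBImage::imageData(cimg)
  if (length(dim(cd)) == 2L) cd <- array(rep(cd, 3L), dim = c(dim(cd), 3L))
  if (!all(dim(cd)[1:2] == c(cols, rows)))
    wm_stop("wm_format_error", "depth and color image dimensions differ")
  rgb <- array(0L, dim = c(rows, cols, 3L))
  for (k in 1:3) rgb[, , k] <- as.integer(round(t(cd[, , k]) * 255))
  px <- as.numeric(meta$pitch_mm[[1L]]); py <- as.numeric(meta$pitch_mm[[2L]])
  ox <- if (!is.null(meta$origin_mm)) as.numeric(meta$origin_mm[[1L]]) else 0
  oy <- if (!is.null(meta$origin_mm)) as.numeric(meta$origin_mm[[2L]]) else 0
  organized_surface(ox + (seq_len(cols) - 1L) * px,
                    oy + (seq_len(rows) - 1L) * py, z, rgb,
                    pitch_x = px, pitch_y = py)
}
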