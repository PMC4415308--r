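# Operator-input files: seed label PNGs, manual-stroke JSON, edge export.

#' Read / write seed label images
#'
#' Seeds are stored as 8-bit gray PNG with pixel values 0 (unknown),
#' 1 (wound) and 2 (background), the file analogue of the operator's painted
#' regions.
#'
#' @param path PNG file path.
#' @return [seed_labels()] matrix.
#' @export
read_seeds <- function(path) {
  if (!file.exists(path)) wm_stop("wm_format_error", "file not found: %s", path)
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) d <- d[, , 1L]
  seed_labels(round(t(d) * 255))
}

#' @rdname read_seeds
#' @param seeds a [seed_labels()] matrix.
#' @export
write_seeds <- function(seeds, path) {
  seeds <- seed_labels(seeds)
  EBImage::writeImage(EBImage::Image(t(unclass(seeds)) / 255), path,
                      type = "png", bits = 8L)
  invisible(path)
}

#' Derive generous seed regions from a wound mask
#'
#' Emulates the operator's two painted regions: the mask eroded by
#' `erode_px` becomes the definite-wound region, the complement of the mask
#' dilated by `dilate_px` becomes the definite-background region.
#'
#' @param mask logical wound mask.
#' @param erode_px,dilate_px disc radii in pixels.
#' @return A [seed_labels()] matrix.
#' @export
make_seeds <- function(mask, erode_px = 4L, dilate_px = 8L) {
  m <- EBImage::Image(t(mask * 1))
  er <- t(EBImage::imageData(EBImage::erode(
    m, EBImage::makeBrush(2L * erode_px + 1L, "disc")))) > 0
  di <- t(EBImage::imageData(EBImage::dilate(
    m, EBImage::makeBrush(2L * dilate_px + 1L, "disc")))) > 0
  out <- matrix(0L, nrow(mask), ncol(mask))
  out[er] <- 1L
  out[!di] <- 2L
  seed_labels(out)
}

#' Read manual closing strokes
#'
#' Strokes are a JSON list of polylines; each polyline is a list of
#' `[row, col]` grid positions.
#'
#' @param path JSON file.
#' @return List of n x 2 matrices.
#' @export
read_strokes <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.matrix(raw)) raw <- list(raw)
  lapply(raw, function(p) matrix(as.numeric(unlist(p)), ncol = 2L,
                                 byrow = !is.matrix(p)))
}

#' Export a wound edge to JSON or CSV
#'
#' @param edge a [wound_edge()].
#' @param path output file; format chosen by extension (.json or .csv).
#' @export
write_edge <- function(edge, path) {
  stopifnot(inherits(edge, "wound_edge"))
  df <- data.frame(x_mm = edge$xy[, 1L], y_mm = edge$xy[, 2L])
  if (!is.null(edge$rc)) { df$row <- edge$rc[, 1L]; df$col <- edge$rc[, 2L] }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(df, path, digits = NA)
  } else {
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a wound edge written by [write_edge()]
#' @param path JSON or CSV file.
#' @return A [wound_edge()].
#' @export
read_edge <- function(path) {
  df <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else utils::read.csv(path)
  rc <- if (all(c("row", "col") %in% names(df))) cbind(df$row, df$col) else NULL
  wound_edge(cbind(df$x_mm, df$y_mm), rc)
}
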