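# GrowCut: cellular-automaton segmentation from operator seed regions.

#' Seed labels for GrowCut/GrabCut
#'
#' @param labels integer matrix: 0 = UNKNOWN, 1 = WOUND, 2 = BACKGROUND.
#' @return Classed `seed_labels` matrix.
#' @export
seed_labels <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% 0:2))
    wm_stop("wm_format_error", "seed labels must be 0 (unknown), 1 (wound), 2 (background)")
  structure(labels, class = c("seed_labels", "matrix"))
}

check_seeds <- function(seeds, rows, cols) {
  if (!all(dim(seeds) == c(rows, cols)))
    wm_stop("wm_format_error", "seed image dimensions differ from the color image")
  if (!any(seeds == 1L)) wm_stop("wm_seed_missing", "no WOUND seed pixels")
  if (!any(seeds == 2L)) wm_stop("wm_seed_missing", "no BACKGROUND seed pixels")
  invisible(TRUE)
}

#' Wound segmentation via the GrowCut cellular automaton
#'
#' Seeded cells start with strength 1; an 8-neighbor q conquers cell p when
#' `g(||C_p - C_q||) * theta_q > theta_p` with `g(d) = 1 - d / d_max`, `d_max`
#' the maximal attainable RGB distance. Labels and strengths are updated
#' synchronously until no cell is relabeled (or `max_iter`). The WOUND label
#' region, reduced to its largest 4-connected component, is the mask.
#'
#' @param image a `color_image`.
#' @param seeds a [seed_labels()] matrix.
#' @param max_iter iteration cap; non-convergence returns the current state
#'   with a warning.
#' @return Logical wound mask with attribute `converged`.
#' @export
segment_growcut <- function(image, seeds, max_iter = 500L) {
  stopifnot(inherits(image, "color_image"))
  seeds <- seed_labels(seeds)
  check_seeds(seeds, image$rows, image$cols)
  nr <- image$rows; nc <- image$cols
  lab <- matrix(as.integer(seeds), nr, nc)
  theta <- matrix(0, nr, nc)
  theta[lab > 0L] <- 1
  d_max <- sqrt(3) * 255
  R <- image$rgb[, , 1L]; G <- image$rgb[, , 2L]; B <- image$rgb[, , 3L]
  shifts <- rbind(c(-1L, -1L), c(-1L, 0L), c(-1L, 1L), c(0L, -1L),
                  c(0L, 1L), c(1L, -1L), c(1L, 0L), c(1L, 1L))
  # color-similarity maps g(||C_p - C_q||) are constant: precompute per shift
  gmaps <- vector("list", nrow(shifts))
  for (k in seq_len(nrow(shifts))) {
    dr <- shifts[k, 1L]; dc <- shifts[k, 2L]
    d <- sqrt((R - shift_mat(R, dr, dc, fill = NA))^2 +
                (G - shift_mat(G, dr, dc, fill = NA))^2 +
                (B - shift_mat(B, dr, dc, fill = NA))^2)
    g <- 1 - d / d_max
    g[!is.finite(g)] <- 0
    gmaps[[k]] <- g
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    best <- theta
    best_lab <- lab
    changed <- matrix(FALSE, nr, nc)
    for (k in seq_len(nrow(shifts))) {
      cand <- gmaps[[k]] * shift_mat(theta, shifts[k, 1L], shifts[k, 2L])
      cl <- shift_mat(lab, shifts[k, 1L], shifts[k, 2L])
      win <- cand > best & cl > 0L
      if (any(win)) {
        best[win] <- cand[win]
        best_lab[win] <- cl[win]
        changed <- changed | win
      }
    }
    if (!any(changed)) { converged <- TRUE; break }
    theta <- best
    lab <- best_lab
  }
  if (!converged)
    wm_warn("GrowCut did not converge within %d iterations", max_iter)
  mask <- largest_component(lab == 1L) & image$valid
  attr(mask, "converged") <- converged
  mask
}
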