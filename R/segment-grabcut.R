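# GrabCut-style iterative foreground extraction: Gaussian mixture color
# models for wound/background re-estimated alternately with an s-t min-cut
# labeling (igraph max-flow). WOUND and BACKGROUND seeds are hard constraints.

# fit a K-component full-covariance Gaussian mixture by (seeded) k-means
fit_gmm <- function(X, K = 5L) {
  K <- min(K, max(1L, nrow(unique(X))))
  if (nrow(X) <= K) {
    cl <- seq_len(nrow(X))
    centers <- X
  } else {
    km <- suppressWarnings(stats::kmeans(X, centers = K, iter.max = 30L,
                                         nstart = 1L))
    cl <- km$cluster
    centers <- km$centers
  }
  comps <- lapply(seq_len(max(cl)), function(k) {
    Xk <- X[cl == k, , drop = FALSE]
    mu <- colMeans(Xk)
    S <- if (nrow(Xk) > 3L) stats::cov(Xk) else diag(3)
    S <- S + diag(3) * 1e-2  # regularize
    cS <- chol(S)
    list(mu = mu, chol_inv = backsolve(cS, diag(3)),
         logdet = 2 * sum(log(diag(cS))), w = nrow(Xk) / nrow(X))
  })
  comps[vapply(comps, function(c) c$w > 0, logical(1L))]
}

# per-pixel data cost: -log of the best-component weighted density
gmm_neglog <- function(X, gmm) {
  n <- nrow(X)
  best <- rep(Inf, n)
  for (cp in gmm) {
    D <- sweep(X, 2, cp$mu) %*% cp$chol_inv
    nll <- 0.5 * rowSums(D^2) + 0.5 * cp$logdet - log(cp$w) +
      1.5 * log(2 * pi)
    best <- pmin(best, nll)
  }
  best
}

#' Wound segmentation via iterative graph-cut foreground extraction
#'
#' The GrabCut scheme: seed regions initialize wound/background Gaussian
#' mixture color models (5 components each, full covariance); each iteration
#' recomputes per-pixel data costs, solves the s-t min cut of the 8-connected
#' pixel graph with contrast-weighted smoothness terms, and refits the
#' mixtures on the resulting partition. Seeded pixels are hard constraints
#' and can never change label. Deterministic given `seed`.
#'
#' @param image a `color_image`.
#' @param seeds a [seed_labels()] matrix (1 = WOUND, 2 = BACKGROUND hard).
#' @param n_iter number of model/cut alternations (>= 1).
#' @param gamma smoothness weight.
#' @param K mixture components per class.
#' @param seed RNG seed for the k-means initialization.
#' @return Logical wound mask (largest 4-connected component).
#' @export
segment_grabcut <- function(image, seeds, n_iter = 5L, gamma = 50,
                            K = 5L, seed = 1L) {
  stopifnot(inherits(image, "color_image"))
  seeds <- seed_labels(seeds)
  check_seeds(seeds, image$rows, image$cols)
  if (n_iter < 1L) wm_stop("wm_format_error", "n_iter must be >= 1")
  nr <- image$rows; nc <- image$cols; n <- nr * nc
  X <- cbind(as.numeric(image$rgb[, , 1L]),
             as.numeric(image$rgb[, , 2L]),
             as.numeric(image$rgb[, , 3L]))
  fg_seed <- as.vector(seeds == 1L)
  bg_seed <- as.vector(seeds == 2L)
  # n-links: 8-neighborhood, contrast-adaptive weights
  R <- image$rgb[, , 1L]; G <- image$rgb[, , 2L]; B <- image$rgb[, , 3L]
  idm <- matrix(seq_len(n), nr, nc)
  pair_sets <- list(
    list(a = idm[, 1:(nc - 1), drop = FALSE],
         b = idm[, 2:nc, drop = FALSE], d = 1),
    list(a = idm[1:(nr - 1), , drop = FALSE],
         b = idm[2:nr, , drop = FALSE], d = 1),
    list(a = idm[1:(nr - 1), 1:(nc - 1), drop = FALSE],
         b = idm[2:nr, 2:nc, drop = FALSE], d = sqrt(2)),
    list(a = idm[1:(nr - 1), 2:nc, drop = FALSE],
         b = idm[2:nr, 1:(nc - 1), drop = FALSE], d = sqrt(2)))
  pairs <- lapply(pair_sets, function(ps) cbind(as.vector(ps$a), as.vector(ps$b)))
  ep <- do.call(rbind, pairs)
  d2 <- rowSums((X[ep[, 1L], ] - X[ep[, 2L], ])^2)
  dist <- rep(vapply(pair_sets, `[[`, numeric(1L), "d"),
              vapply(pairs, nrow, integer(1L)))
  beta <- 1 / (2 * max(mean(d2), 1e-9))
  wn <- gamma * exp(-beta * d2) / dist
  u_cap <- 500  # caps -log densities; far beyond any plausible color likelihood
  # seed pixels are hard-constrained: contract them into the terminals so the
  # cut graph only carries the unknown pixels (exact, and much smaller)
  unk <- which(!fg_seed & !bg_seed)
  node <- integer(n)
  node[unk] <- seq_along(unk)
  m <- length(unk)
  a_u <- node[ep[, 1L]]; b_u <- node[ep[, 2L]]
  both <- a_u > 0L & b_u > 0L
  ep_uu <- cbind(a_u[both], b_u[both]); wn_uu <- wn[both]
  # n-links touching a seed fold into the unknown pixel's terminal links
  to_fg <- (a_u > 0L & fg_seed[ep[, 2L]]) | (b_u > 0L & fg_seed[ep[, 1L]])
  to_bg <- (a_u > 0L & bg_seed[ep[, 2L]]) | (b_u > 0L & bg_seed[ep[, 1L]])
  fold <- function(sel) {
    v <- numeric(m)
    if (any(sel)) {
      nd <- pmax(a_u[sel], b_u[sel])
      agg <- rowsum(wn[sel], nd)
      v[as.integer(rownames(agg))] <- agg
    }
    v
  }
  add_s <- fold(to_fg)  # capacity toward the wound terminal
  add_t <- fold(to_bg)
  fg <- fg_seed
  set.seed(seed)
  for (it in if (m > 0L) seq_len(n_iter) else integer()) {
    fg_fit <- if (it == 1L) fg_seed else fg
    bg_fit <- if (it == 1L) bg_seed else !fg
    gmm_fg <- fit_gmm(X[fg_fit, , drop = FALSE], K)
    gmm_bg <- fit_gmm(X[bg_fit, , drop = FALSE], K)
    U_fg <- gmm_neglog(X[unk, , drop = FALSE], gmm_fg)  # cost if labeled wound
    U_bg <- gmm_neglog(X[unk, , drop = FALSE], gmm_bg)
    cap_s <- pmin(U_bg, u_cap) + add_s  # paid when the pixel ends background
    cap_t <- pmin(U_fg, u_cap) + add_t  # paid when the pixel ends wound
    s <- m + 1L; t <- m + 2L
    el <- rbind(cbind(s, seq_len(m)), cbind(seq_len(m), t), ep_uu, ep_uu[, 2:1])
    caps <- c(cap_s, cap_t, wn_uu, wn_uu)
    g <- igraph::graph_from_edgelist(el, directed = TRUE)
    mf <- igraph::max_flow(g, source = s, target = t, capacity = caps)
    src_side <- rep(FALSE, m + 2L)
    src_side[as.integer(mf$partition1)] <- TRUE
    if (!src_side[s]) src_side <- !src_side
    new_fg <- fg_seed
    new_fg[unk] <- src_side[seq_len(m)]
    if (identical(new_fg, fg) && it > 1L) { fg <- new_fg; break }
    fg <- new_fg
  }
  mask <- matrix(fg, nr, nc)
  largest_component(mask) & image$valid
}
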