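# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the implementation paths they
# check: explicit loops, naive definitions.

# Naive separable B3 convolution at dilation `step`, mirror boundaries,
# explicit loops over pixels and taps.
oracle_b3_smooth <- function(x, step) {
  taps <- c(1, 4, 6, 4, 1) / 16
  offs <- c(-2, -1, 0, 1, 2) * step
  nr <- nrow(x); nc <- ncol(x)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 2 - i
      if (i > n) i <- 2 * n - i
    }
    i
  }
  tmp <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    s <- 0
    for (k in 1:5) s <- s + taps[k] * x[refl(r + offs[k], nr), cc]
    tmp[r, cc] <- s
  }
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    s <- 0
    for (k in 1:5) s <- s + taps[k] * tmp[r, refl(cc + offs[k], nc)]
    out[r, cc] <- s
  }
  out
}

# Detail plane j of the a trous transform by repeated naive smoothing.
oracle_detail_plane <- function(x, j) {
  prev <- x
  for (s in seq_len(j)) {
    sm <- oracle_b3_smooth(prev, 2^(s - 1))
    d <- prev - sm
    prev <- sm
  }
  d
}

# Per-pixel box erosion: pixel kept iff the full (2w+1)^2 neighbourhood
# is inside the mask (out-of-bounds counts as background).
oracle_erode_box <- function(mask, w) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    keep <- TRUE
    for (dr in -w:w) for (dc in -w:w) {
      rr <- r + dr; ccc <- cc + dc
      if (rr < 1 || rr > nr || ccc < 1 || ccc > nc || !mask[rr, ccc]) {
        keep <- FALSE
      }
    }
    out[r, cc] <- keep
  }
  out
}

# Exhaustive point-to-polyline distance mask (0-based pixel coords).
oracle_polyline_mask <- function(path, width, shape) {
  seg_dist <- function(p, a, b) {
    v <- b - a
    len2 <- sum(v^2)
    if (len2 == 0) return(sqrt(sum((p - a)^2)))
    t <- max(0, min(1, sum((p - a) * v) / len2))
    sqrt(sum((p - (a + t * v))^2))
  }
  out <- matrix(FALSE, shape[1], shape[2])
  for (r in seq_len(shape[1])) for (cc in seq_len(shape[2])) {
    p <- c(r - 1, cc - 1)
    d <- Inf
    for (s in seq_len(nrow(path) - 1)) {
      d <- min(d, seg_dist(p, path[s, ], path[s + 1, ]))
    }
    out[r, cc] <- d <= width / 2
  }
  out
}

# Bound fraction by bisection on the free-ligand mass-action equation:
# solve for free ligand Lf in [0, L] with (L - Lf) = T * Lf / (kd + Lf)
# (complex = T_free * L_free / kd), then f = complex / T.
oracle_fraction_bound <- function(L, kd, T) {
  g <- function(Lf) (L - Lf) - T * Lf / (kd + Lf)
  lo <- 0; hi <- L
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  Lf <- (lo + hi) / 2
  (L - Lf) / T    # complex / T
}

# Match detected centroids to true centers within `tol` px (greedy on
# nearest neighbour); returns recall, precision, mean matched error.
match_detections <- function(true_centers, det_centers, tol = 2) {
  n_true <- nrow(true_centers); n_det <- nrow(det_centers)
  if (n_det == 0) return(list(recall = 0, precision = NA_real_, err = NA_real_))
  d <- outer(seq_len(n_true), seq_len(n_det), Vectorize(function(i, j) {
    sqrt(sum((true_centers[i, ] - det_centers[j, ])^2))
  }))
  nearest <- apply(d, 1, min)
  recall <- mean(nearest <= tol)
  precision <- mean(apply(d, 2, min) <= tol)
  list(recall = recall, precision = precision,
       err = mean(nearest[nearest <= tol]))
}
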