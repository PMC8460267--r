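# Independent brute-force oracles used to cross-check the fast implementations.

# O(n^2) pair correlation: double loop over all ordered node pairs, binned by
# rounded separation in grid-spacing units.  Mirrors the definition, not the
# FFT implementation.
brute_force_correlation <- function(z, spacing) {
  n1 <- nrow(z); n2 <- ncol(z)
  pos <- cbind(rep(seq_len(n1), times = n2), rep(seq_len(n2), each = n1))
  v <- as.vector(z)
  ok <- !is.na(v)
  pos <- pos[ok, , drop = FALSE]; v <- v[ok]
  n <- length(v)
  maxbin <- ceiling(sqrt((n1 - 1)^2 + (n2 - 1)^2)) + 1L
  num <- cnt <- s1 <- s2 <- numeric(maxbin + 1L)
  for (i in seq_len(n)) {
    d <- sqrt((pos[, 1] - pos[i, 1])^2 + (pos[, 2] - pos[i, 2])^2)
    b <- round(d) + 1L
    g <- rowsum(cbind(v[i] * v, 1, v[i]^2 + 0 * v, v^2), b)
    bins <- as.integer(rownames(g))
    num[bins] <- num[bins] + g[, 1]
    cnt[bins] <- cnt[bins] + g[, 2]
    s1[bins] <- s1[bins] + g[, 3]
    s2[bins] <- s2[bins] + g[, 4]
  }
  keep <- cnt >= 1
  list(r = (which(keep) - 1L) * spacing,
       C = (num / sqrt(s1 * s2))[keep],
       n_pairs = cnt[keep])
}

# O(n^2) k-nearest-neighbour mean distances, plain double loop.
brute_force_knn <- function(xy, k) {
  n <- nrow(xy)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    out[i] <- mean(sort(d[-i])[seq_len(k)])
  }
  out
}

# shift an image by cropping from a larger source, so shifted content is real
crop_shift_pair <- function(big, n, dx, dy, offset = 16L) {
  a <- big[offset:(offset + n - 1), offset:(offset + n - 1)]
  b <- big[(offset - dx):(offset - dx + n - 1), (offset - dy):(offset - dy + n - 1)]
  list(a = a, b = b)
}

rel_l2_mat <- function(est, truth) {
  sqrt(sum((est - truth)^2, na.rm = TRUE) / sum(truth^2, na.rm = TRUE))
}

smooth_texture <- function(n, seed = 1, sigma = 1.5) {
  set.seed(seed)
  sheetmech:::gauss_smooth_small(matrix(runif(n * n), n, n), sigma)
}
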