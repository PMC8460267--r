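#' k-nearest-neighbour interparticle spacing
#'
#' For each point farther than `edge_margin` from the domain boundary, the
#' mean distance to its `k` nearest neighbours is computed; the summary is the
#' mean and sd of these per-point means.  `k = 6` is the natural choice for
#' quasi-hexagonal particle arrays, where each interior particle has six
#' lattice neighbours.
#'
#' @param pattern a [point_pattern] (coordinates in nm).
#' @param k number of neighbours (default 6).
#' @param edge_margin exclusion margin from the domain boundary, nm; `NULL`
#'   defaults to 1.5 times the median nearest-neighbour distance, since
#'   boundary particles lack a full neighbour shell.
#' @return object of class `spacing_summary`: `mean_spacing`, `sd_spacing`,
#'   `per_point_mean_knn`, `n_points`, `k_used`, `edge_margin`.
#' @export
knn_spacing <- function(pattern, k = 6L, edge_margin = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  xy <- pattern$coordinates
  n <- nrow(xy)
  if (n < k + 1) stop_data("need at least k + 1 = ", k + 1, " points, got ", n)
  nn <- knn_distances(xy, k)
  if (is.null(edge_margin)) edge_margin <- 1.5 * stats::median(nn[, 1])
  b <- pattern$domain_bounds
  keep <- xy[, 1] >= b[1] + edge_margin & xy[, 1] <= b[2] - edge_margin &
          xy[, 2] >= b[3] + edge_margin & xy[, 2] <= b[4] - edge_margin
  if (!any(keep)) stop_data("edge_margin excludes every point")
  per_point <- rowMeans(nn[keep, , drop = FALSE])
  structure(list(mean_spacing = mean(per_point),
                 sd_spacing = stats::sd(per_point),
                 per_point_mean_knn = per_point,
                 n_points = sum(keep), k_used = as.integer(k),
                 edge_margin = edge_margin),
            class = "spacing_summary")
}

#' @export
print.spacing_summary <- function(x, ...) {
  cat(sprintf("<spacing_summary> k = %d, n = %d points (edge margin %.3g nm)\n",
              x$k_used, x$n_points, x$edge_margin))
  cat(sprintf("  mean spacing %.4g nm, sd %.4g nm\n", x$mean_spacing,
              if (is.na(x$sd_spacing)) 0 else x$sd_spacing))
  invisible(x)
}

## distances to the k nearest neighbours of every point, chunked so the
## distance matrix never exceeds ~4e6 entries
knn_distances <- function(xy, k) {
  n <- nrow(xy)
  chunk <- max(1L, floor(4e6 / n))
  out <- matrix(NA_real_, n, k)
  x <- xy[, 1]; y <- xy[, 2]
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(x[s:e], x, "-")^2 + outer(y[s:e], y, "-")^2
    d2[cbind(seq_len(e - s + 1L), s:e)] <- Inf  # exclude self
    for (r in seq_len(e - s + 1L))
      out[s + r - 1L, ] <- sqrt(sort.int(d2[r, ], partial = seq_len(k))[seq_len(k)])
  }
  out
}

#' Detect sub-pixel spots in a single-channel image
#'
#' Local-maximum detection above a relative threshold followed by intensity
#' centroid refinement in a window around each maximum.
#'
#' @param image numeric matrix.
#' @param expected_sigma expected spot sd, px (sets the refinement window and
#'   the minimum maxima separation).
#' @param threshold relative threshold in (0, 1): maxima below
#'   `min + threshold * (max - min)` of the smoothed image are discarded.
#' @param px_size optional calibration to return nm coordinates
#'   (default 1: positions in px).
#' @return a [point_pattern] of spot centres (0-based, in units of `px_size`).
#' @export
detect_spots <- function(image, expected_sigma = 1.5, threshold = 0.2,
                         px_size = 1) {
  img <- gauss_smooth_small(image, expected_sigma / 2)
  lo <- min(img); hi <- max(img)
  thr <- lo + threshold * (hi - lo)
  n1 <- nrow(img); n2 <- ncol(img)
  # strict local maxima over the 8-neighbourhood
  ok <- matrix(FALSE, n1, n2)
  ok[2:(n1 - 1), 2:(n2 - 1)] <- TRUE
  cand <- which(ok & img > thr)
  if (length(cand)) {
    i <- (cand - 1) %% n1 + 1; j <- (cand - 1) %/% n1 + 1
    ismax <- rep(TRUE, length(cand))
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ismax <- ismax & img[cand] >= img[cbind(i + di, j + dj)]
    }
    cand <- cand[ismax]
  }
  if (length(cand) == 0) {
    warning("no spots detected")
    return(point_pattern(matrix(numeric(0), 0, 2),
                         domain_bounds = c(0, (n1 - 1) * px_size,
                                           0, (n2 - 1) * px_size)))
  }
  i <- (cand - 1) %% n1 + 1; j <- (cand - 1) %/% n1 + 1
  r <- max(2L, ceiling(2 * expected_sigma))
  base <- min(image)
  centr <- t(vapply(seq_along(cand), function(s) {
    i0 <- max(1L, i[s] - r); i1 <- min(n1, i[s] + r)
    j0 <- max(1L, j[s] - r); j1 <- min(n2, j[s] + r)
    w <- image[i0:i1, j0:j1] - base
    w[w < 0] <- 0
    tot <- sum(w)
    if (tot == 0) return(c(i[s], j[s]))
    c(sum(w * (i0:i1)) / tot, sum(t(w) * (j0:j1)) / tot)
  }, numeric(2)))
  point_pattern((centr - 1) * px_size,
                domain_bounds = c(0, (n1 - 1) * px_size, 0, (n2 - 1) * px_size))
}

#' Write / read point patterns as CSV (columns x_nm, y_nm)
#' @param pattern a [point_pattern]; `path` file path.
#' @return `read_point_pattern` returns a [point_pattern].
#' @export
write_point_pattern <- function(pattern, path) {
  utils::write.csv(as.data.frame(pattern$coordinates), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_point_pattern
#' @param path CSV path.
#' @export
read_point_pattern <- function(path) {
  df <- utils::read.csv(path)
  point_pattern(as.matrix(df[, c("x_nm", "y_nm")]))
}
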