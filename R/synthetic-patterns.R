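#' Planar point pattern (nanoparticle coordinates)
#'
#' @param coordinates two-column matrix or data.frame of positions, nm.
#' @param domain_bounds rectangle `c(xmin, xmax, ymin, ymax)` in nm; defaults
#'   to the bounding box.
#' @return object of class `point_pattern`.
#' @export
point_pattern <- function(coordinates, domain_bounds = NULL) {
  xy <- as.matrix(coordinates)
  if (ncol(xy) != 2) stop_invalid("coordinates must have two columns")
  colnames(xy) <- c("x_nm", "y_nm")
  if (is.null(domain_bounds)) {
    domain_bounds <- if (nrow(xy) > 0)
      c(range(xy[, 1]), range(xy[, 2])) else c(0, 0, 0, 0)
  }
  structure(list(coordinates = xy, domain_bounds = domain_bounds),
            class = "point_pattern")
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d points in [%.4g, %.4g] x [%.4g, %.4g] nm\n",
              nrow(x$coordinates), x$domain_bounds[1], x$domain_bounds[2],
              x$domain_bounds[3], x$domain_bounds[4]))
  invisible(x)
}

#' @export
plot.point_pattern <- function(x, ...) {
  graphics::plot(x$coordinates, asp = 1, pch = 16, cex = 0.4,
                 xlab = "x (nm)", ylab = "y (nm)", ...)
  invisible(x)
}

#' Generate a jittered quasi-hexagonal nanoparticle pattern
#'
#' Points of a triangular lattice with lattice constant `spacing`, each
#' perturbed independently by isotropic Gaussian noise of standard deviation
#' `jitter_sd`.  Emulates quasi-hexagonal gold nanoparticle arrays at nominal
#' 35/50/70 nm interparticle spacing.
#'
#' @param spacing lattice constant, nm.
#' @param jitter_sd positional noise sd, nm.
#' @param n_points number of points (>= 7).
#' @param seed integer seed.
#' @return a [point_pattern].
#' @export
gen_hex_pattern <- function(spacing, jitter_sd = 0, n_points = 625L, seed = 1L) {
  if (spacing <= 0) stop_invalid("spacing must be > 0")
  if (jitter_sd < 0) stop_invalid("jitter_sd must be >= 0")
  if (n_points < 7) stop_invalid("n_points must be >= 7")
  nx <- ceiling(sqrt(n_points / (sqrt(3) / 2)))
  ny <- ceiling(n_points / nx)
  ij <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  ij <- ij[seq_len(n_points), , drop = FALSE]
  x <- ij$i * spacing + (ij$j %% 2) * spacing / 2
  y <- ij$j * spacing * sqrt(3) / 2
  if (jitter_sd > 0) {
    with_seed(derive_seed(seed, "hex_pattern"), {
      x <- x + stats::rnorm(n_points, sd = jitter_sd)
      y <- y + stats::rnorm(n_points, sd = jitter_sd)
    })
  }
  point_pattern(cbind(x, y))
}
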