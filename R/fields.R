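#' Planar vector field on a regular grid
#'
#' Container for displacement or velocity fields sampled on a regular grid,
#' as produced by PIV or the synthetic generators.  Components are stored as
#' matrices indexed `[ix, iy]` with node positions in micrometres.
#'
#' @param x,y numeric vectors of node positions along each axis (um), strictly
#'   increasing and evenly spaced.
#' @param u,v matrices of the two in-plane components, `length(x)` by
#'   `length(y)`.  Units are either pixels (`units = "px"`), micrometres
#'   (`"um"`) or micrometres per hour (`"um/hr"`).
#' @param units unit flag for the components (`"Pa"` marks traction fields).
#' @param px_size pixel calibration, um/px (optional, needed for unit
#'   conversions).
#' @param dt frame interval in minutes (optional; present for velocity fields
#'   derived from movies).
#' @param quality optional matrix of per-node correlation quality in `[0, 1]`;
#'   `NA` components mark invalid nodes.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(x, y, u, v, units = c("um", "px", "um/hr", "Pa"),
                         px_size = NULL, dt = NULL, quality = NULL) {
  units <- match.arg(units)
  u <- as.matrix(u); v <- as.matrix(v)
  stopifnot(length(x) == nrow(u), length(y) == ncol(u),
            all(dim(u) == dim(v)))
  if (length(x) > 1 && diff(range(diff(x))) > 1e-6 * mean(diff(x)))
    stop_invalid("grid must be regular along x")
  if (length(y) > 1 && diff(range(diff(y))) > 1e-6 * mean(diff(y)))
    stop_invalid("grid must be regular along y")
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    stopifnot(all(dim(quality) == dim(u)))
  }
  structure(list(x = as.numeric(x), y = as.numeric(y), u = u, v = v,
                 units = units, px_size = px_size, dt = dt, quality = quality),
            class = "vector_field")
}

grid_spacing <- function(field) {
  if (length(field$x) > 1) diff(field$x[1:2]) else diff(field$y[1:2])
}

#' @export
print.vector_field <- function(x, ...) {
  cat(sprintf("<vector_field> %d x %d nodes, spacing %.3g um, units %s\n",
              length(x$x), length(x$y), grid_spacing(x), x$units))
  mag <- sqrt(x$u^2 + x$v^2)
  cat(sprintf("  |v|: mean %.4g, max %.4g; invalid nodes: %d\n",
              mean(mag, na.rm = TRUE), max(mag, na.rm = TRUE), sum(is.na(x$u))))
  invisible(x)
}

#' @export
as.data.frame.vector_field <- function(x, ...) {
  data.frame(x_um = rep(x$x, times = length(x$y)),
             y_um = rep(x$y, each = length(x$x)),
             u = as.vector(x$u), v = as.vector(x$v),
             quality = if (is.null(x$quality)) NA_real_ else as.vector(x$quality))
}

#' @export
plot.vector_field <- function(x, scale = NULL, ...) {
  df <- as.data.frame(x)
  mag <- sqrt(df$u^2 + df$v^2)
  if (is.null(scale)) {
    m <- stats::quantile(mag, 0.95, na.rm = TRUE)
    scale <- if (m > 0) grid_spacing(x) / m else 1
  }
  graphics::plot(df$x_um, df$y_um, type = "n", asp = 1,
                 xlab = "x (um)", ylab = "y (um)", ...)
  ok <- !is.na(df$u) & mag > 0
  graphics::arrows(df$x_um[ok], df$y_um[ok],
                   df$x_um[ok] + scale * df$u[ok], df$y_um[ok] + scale * df$v[ok],
                   length = 0.03, col = "steelblue4")
  invisible(x)
}

#' Convert a displacement field between pixel and micrometre units
#' @param field a [vector_field].
#' @param to target units, `"um"` or `"px"`.
#' @return the converted field.
#' @export
convert_units <- function(field, to = c("um", "px")) {
  to <- match.arg(to)
  if (field$units == to) return(field)
  if (is.null(field$px_size)) stop_invalid("px_size needed for unit conversion")
  f <- if (to == "um") field$px_size else 1 / field$px_size
  field$u <- field$u * f; field$v <- field$v * f
  field$units <- to
  field
}

#' In-plane monolayer stress tensor field
#'
#' Symmetric 2x2 line stress (N/m) per grid node with derived average normal
#' stress, principal values and principal orientation.
#'
#' @param x,y node positions (um).
#' @param sxx,syy,sxy component matrices (N/m).
#' @param gauge additive constant absorbed into the isotropic part when the
#'   field was recovered under a periodic zero-mean gauge (see [msm_solve]).
#' @return An object of class `stress_field` with elements `sxx`, `syy`,
#'   `sxy`, `avg_normal`, `smax`, `smin`, `theta`.
#' @export
stress_field <- function(x, y, sxx, syy, sxy, gauge = 0) {
  sxx <- as.matrix(sxx); syy <- as.matrix(syy); sxy <- as.matrix(sxy)
  stopifnot(length(x) == nrow(sxx), length(y) == ncol(sxx),
            all(dim(sxx) == dim(syy)), all(dim(sxx) == dim(sxy)))
  p <- principal_decomposition_raw(sxx, syy, sxy)
  structure(list(x = as.numeric(x), y = as.numeric(y),
                 sxx = sxx, syy = syy, sxy = sxy,
                 avg_normal = (sxx + syy) / 2,
                 smax = p$smax, smin = p$smin, theta = p$theta,
                 gauge = gauge),
            class = "stress_field")
}

# closed-form 2x2 symmetric eigendecomposition, vectorized over nodes
principal_decomposition_raw <- function(sxx, syy, sxy) {
  mid <- (sxx + syy) / 2
  rad <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  theta <- atan2(2 * sxy, sxx - syy) / 2
  theta <- (theta + pi) %% pi            # fold to [0, pi)
  theta[rad == 0] <- NA_real_            # isotropic: orientation undefined
  list(smax = mid + rad, smin = mid - rad, theta = theta)
}

#' Principal decomposition of a stress tensor field
#'
#' Per-node eigenvalues and principal orientation of the symmetric in-plane
#' stress tensor.  The orientation is the angle of the major principal axis in
#' `[0, pi)` and is flagged `NA` where the tensor is isotropic.
#'
#' @param stress a [stress_field].
#' @return list with matrices `smax`, `smin`, `theta`.
#' @export
principal_decomposition <- function(stress) {
  stopifnot(inherits(stress, "stress_field"))
  principal_decomposition_raw(stress$sxx, stress$syy, stress$sxy)
}

#' @export
print.stress_field <- function(x, ...) {
  cat(sprintf("<stress_field> %d x %d nodes, spacing %.3g um\n",
              length(x$x), length(x$y), diff(x$x[1:2])))
  cat(sprintf("  avg normal stress (N/m): mean %.4g, sd %.4g (gauge %.3g)\n",
              mean(x$avg_normal), stats::sd(as.vector(x$avg_normal)), x$gauge))
  invisible(x)
}

#' @export
as.data.frame.stress_field <- function(x, ...) {
  data.frame(x_um = rep(x$x, times = length(x$y)),
             y_um = rep(x$y, each = length(x$x)),
             sxx = as.vector(x$sxx), syy = as.vector(x$syy),
             sxy = as.vector(x$sxy), avg_normal = as.vector(x$avg_normal),
             smax = as.vector(x$smax), smin = as.vector(x$smin),
             theta = as.vector(x$theta))
}

#' @export
plot.stress_field <- function(x, what = "avg_normal", ...) {
  z <- x[[what]]
  graphics::image(x$x, x$y, z, asp = 1, xlab = "x (um)", ylab = "y (um)",
                  col = grDevices::hcl.colors(64, "viridis"),
                  main = paste0(what, " (N/m)"), ...)
  invisible(x)
}
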