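#' Decompose a velocity field into axial and lateral components
#'
#' Projects every vector onto the migration axis (axial component) and its
#' perpendicular (lateral component), and forms the lateral fluctuation
#' `v_ij = lateral_ij - mean(lateral)`.  The fluctuating part of the
#' component perpendicular to the sheet-migration direction is what the
#' lateral correlation analysis operates on; its spatial mean is removed so
#' `mean(v_ij) = 0` exactly by construction.  Invalid (`NA`) PIV nodes are
#' excluded from the mean and stay `NA`.
#'
#' @param field a [vector_field] (velocities).
#' @param migration_direction nonzero planar vector giving the direction of
#'   sheet migration.
#' @return object of class `decomposed_field`: matrices `axial`, `lateral`,
#'   `fluctuation`, scalar `lateral_mean`, the unit `direction`, and the
#'   node coordinates `x`, `y` (um).
#' @export
decompose_velocity <- function(field, migration_direction = c(1, 0)) {
  stopifnot(inherits(field, "vector_field"))
  nrm <- sqrt(sum(migration_direction^2))
  if (nrm == 0) stop_invalid("migration_direction must be nonzero")
  e_ax <- migration_direction / nrm
  e_lat <- c(-e_ax[2], e_ax[1])
  axial <- field$u * e_ax[1] + field$v * e_ax[2]
  lateral <- field$u * e_lat[1] + field$v * e_lat[2]
  if (all(is.na(lateral))) stop_data("all nodes invalid")
  lm <- mean(lateral, na.rm = TRUE)
  structure(list(axial = axial, lateral = lateral,
                 fluctuation = lateral - lm, lateral_mean = lm,
                 direction = e_ax, x = field$x, y = field$y,
                 units = field$units),
            class = "decomposed_field")
}

#' @export
print.decomposed_field <- function(x, ...) {
  cat(sprintf("<decomposed_field> %d x %d nodes (%s)\n",
              nrow(x$axial), ncol(x$axial), x$units))
  cat(sprintf("  mean axial %.4g, mean lateral %.4g, fluctuation sd %.4g\n",
              mean(x$axial, na.rm = TRUE), x$lateral_mean,
              stats::sd(as.vector(x$fluctuation), na.rm = TRUE)))
  invisible(x)
}

#' Radially binned spatial autocorrelation curve
#'
#' @param r bin-centre separations (um), `C` correlation values, `n_pairs`
#'   pair counts, `threshold` the crossing threshold used by
#'   [correlation_length].
#' @return object of class `correlation_curve` with the threshold crossing
#'   precomputed (`correlation_length`, `NA` when the curve never reaches
#'   the threshold in range -- right-censored at the maximum separation).
#' @export
correlation_curve <- function(r, C, n_pairs, threshold = 0.01) {
  keep <- n_pairs >= 1
  obj <- structure(list(r = r[keep], C = C[keep], n_pairs = n_pairs[keep],
                        threshold = threshold),
                   class = "correlation_curve")
  obj$correlation_length <- crossing_length(obj$r, obj$C, threshold)
  obj
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %d bins, r in [%.3g, %.3g] um\n",
              length(x$r), min(x$r), max(x$r)))
  if (is.na(x$correlation_length))
    cat(sprintf("  no C(r) = %.3g crossing in range (right-censored at %.4g um)\n",
                x$threshold, max(x$r)))
  else
    cat(sprintf("  correlation length (C = %.3g crossing): %.4g um\n",
                x$threshold, x$correlation_length))
  invisible(x)
}

#' @export
plot.correlation_curve <- function(x, ...) {
  graphics::plot(x$r, x$C, type = "l", xlab = "r (um)", ylab = "C(r)", ...)
  graphics::abline(h = x$threshold, lty = 3)
  if (!is.na(x$correlation_length))
    graphics::abline(v = x$correlation_length, lty = 3, col = "red3")
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(r_um = x$r, C = x$C, n_pairs = x$n_pairs)
}

#' Finite-field plateau correction of a correlation curve
#'
#' Subtracting the sample mean of a fluctuation field removes part of its
#' covariance: over a window of side `L` the measured curve sits below the
#' true one by a deficit `delta ~ integral of C / L^2` (about
#' `4 pi l^2 / L^2` for a Gaussian correlation of scale `l`), which matters
#' precisely at the deep 0.01 threshold.  The deficit appears as a negative
#' plateau at separations beyond the correlation range.
#'
#' The plateau is estimated from the exact pair-sum identity of a
#' mean-subtracted field: the sum of all ordered pairwise products is
#' `(sum v)^2 = 0`, so the pair-count-weighted sum of `C` over all bins
#' vanishes (up to per-bin normalizer variation).  The deficit is therefore
#' `p = -sum_{r < r0} N_b C_b / sum_{r >= r0} N_b`, computed from the
#' well-measured short-separation bins rather than the noisy tail, with
#' `r0 = from * max(r)`.  The curve is rescaled to `(C - p) / (1 - p)`.
#' Used when recovering a generator's correlation scale against the
#' infinite-domain closed form; the uncorrected curve is what the plain
#' estimator reports.
#'
#' @param curve a [correlation_curve].
#' @param from start of the plateau region as a fraction of the maximum
#'   separation (default 0.35); the correlation range must be well inside
#'   it.
#' @return the corrected [correlation_curve] (threshold crossing
#'   recomputed), with the estimated plateau attached as attribute
#'   `"plateau"`.
#' @export
plateau_correct <- function(curve, from = 0.35) {
  stopifnot(inherits(curve, "correlation_curve"))
  sel <- curve$r >= from * max(curve$r)
  p <- -sum(curve$C[!sel] * curve$n_pairs[!sel]) / sum(curve$n_pairs[sel])
  out <- correlation_curve(curve$r, (curve$C - p) / (1 - p), curve$n_pairs,
                           curve$threshold)
  attr(out, "plateau") <- p
  out
}

#' Average correlation curves over realizations
#'
#' Pairwise-count-weighted average of curves sharing a common bin grid, the
#' standard way to stabilize the deep tail before locating a threshold
#' crossing.
#'
#' @param curves list of [correlation_curve]s on identical bins.
#' @return a [correlation_curve].
#' @export
average_correlation <- function(curves) {
  stopifnot(length(curves) >= 1)
  r <- sort(unique(unlist(lapply(curves, `[[`, "r"))))
  num <- den <- numeric(length(r))
  for (cv in curves) {
    ix <- match(round(cv$r, 9), round(r, 9))
    if (anyNA(ix)) stop_invalid("curves must share a common bin spacing")
    num[ix] <- num[ix] + cv$C * cv$n_pairs
    den[ix] <- den[ix] + cv$n_pairs
  }
  keep <- den > 0
  correlation_curve(r[keep], num[keep] / den[keep],
                    round(den[keep] / length(curves)),
                    curves[[1]]$threshold)
}

## first downward threshold crossing, linearly interpolated
crossing_length <- function(r, C, threshold) {
  below <- which(C < threshold)
  if (length(below) == 0) return(NA_real_)
  k <- below[1]
  if (k == 1) return(r[1])
  r0 <- r[k - 1]; r1 <- r[k]; c0 <- C[k - 1]; c1 <- C[k]
  r0 + (c0 - threshold) / (c0 - c1) * (r1 - r0)
}

## Core binned pair-correlation engine.  For scalar input z (deviations
## already taken), computes per radial bin b:
##   num(b)  = sum over ordered pairs (i,j) with |r_i - r_j| in bin b of z_i z_j
##   n(b)    = pair count
##   s1(b), s2(b) = sums of z_i^2 and z_j^2 over the same ordered pairs
## and C(b) = num / sqrt(s1 * s2), the discrete form of
## <z(r') z(r' + r)> / sqrt(<z(r')^2> <z(r' + r)^2>).  Multi-channel input
## (list of matrices) sums numerators over channels and uses the squared
## channel norm in the normalizer.  All sums run over every valid ordered
## pair via FFT cross-correlation, which is exactly the brute-force double
## loop up to floating-point roundoff.
binned_pair_correlation <- function(z_list, spacing) {
  n1 <- nrow(z_list[[1]]); n2 <- ncol(z_list[[1]])
  valid <- Reduce(`&`, lapply(z_list, function(z) !is.na(z)))
  zm <- lapply(z_list, function(z) { z[!valid] <- 0; z })
  q2 <- Reduce(`+`, lapply(zm, function(z) z^2))
  ind <- matrix(0, n1, n2); ind[valid] <- 1
  num <- Reduce(`+`, lapply(zm, function(z) xcorr_all_lags(z, z)))
  cnt <- xcorr_all_lags(ind, ind)
  s1 <- xcorr_all_lags(q2, ind)
  s2 <- xcorr_all_lags(ind, q2)
  # radial bin index of every lag (bin width = one grid spacing)
  dxs <- (-(n1 - 1)):(n1 - 1)
  dys <- (-(n2 - 1)):(n2 - 1)
  rad <- sqrt(outer(dxs^2, dys^2, `+`))
  bin <- round(rad)
  nb <- max(bin) + 1L
  bf <- factor(bin, levels = 0:(nb - 1L))
  tab <- function(m) as.numeric(tapply(m, bf, sum, default = 0))
  numb <- tab(num); cntb <- round(tab(cnt)); s1b <- tab(s1); s2b <- tab(s2)
  C <- ifelse(s1b > 0 & s2b > 0, numb / sqrt(s1b * s2b), NA_real_)
  list(r = (0:(nb - 1L)) * spacing, C = C, n_pairs = cntb)
}

#' Lateral velocity autocorrelation function
#'
#' Spatial autocorrelation of the lateral velocity fluctuations,
#' `C(r) = <v(r') v(r' + r)> / [<v(r')^2> <v(r' + r)^2>]^(1/2)`,
#' radially binned with bin width equal to one grid spacing (pairs assigned
#' by rounded Euclidean separation).  `C(0) = 1` whenever the field has
#' positive variance.
#'
#' @param v a `decomposed_field` (its `fluctuation` matrix is used) or a
#'   plain matrix of lateral fluctuations.
#' @param spacing grid spacing in um (taken from the field when available).
#' @param threshold crossing threshold for the correlation length
#'   (default 0.01).
#' @return a [correlation_curve].
#' @export
velocity_correlation <- function(v, spacing = NULL, threshold = 0.01) {
  if (inherits(v, "decomposed_field")) {
    spacing <- spacing %||% diff(v$x[1:2])
    v <- v$fluctuation
  }
  if (is.null(spacing)) stop_invalid("spacing required for matrix input")
  if (sum(!is.na(v)) < 2) stop_data("need at least 2 valid nodes")
  if (stats::var(as.vector(v), na.rm = TRUE) == 0)
    stop_data("zero-variance fluctuation field: correlation undefined")
  b <- binned_pair_correlation(list(v), spacing)
  correlation_curve(b$r, b$C, b$n_pairs, threshold)
}

#' Spatial autocorrelation of the monolayer stress
#'
#' Scalar mode (default): deviations of the average normal stress from its
#' spatial mean, `delta_sigma = sigma_bar - <sigma_bar>`, correlated as
#' `C(r) = sum_{|ri - rj| = r} delta_sigma_i delta_sigma_j` normalized per
#' radial bin by the pair count and the field variance so that `C(0) = 1`.
#' Nematic mode: the local descriptor is the stress-weighted director with
#' angle doubling, `w = sigma_bar (cos 2 theta, sin 2 theta)` (the doubling
#' respects the +/- orientation symmetry of principal axes); deviation
#' vectors are correlated by dot products under the same normalization.
#'
#' @param stress a [stress_field].
#' @param mode `"scalar"` or `"nematic"`.
#' @param threshold crossing threshold for the correlation length.
#' @return a [correlation_curve].
#' @export
stress_correlation <- function(stress, mode = c("scalar", "nematic"),
                               threshold = 0.01) {
  mode <- match.arg(mode)
  stopifnot(inherits(stress, "stress_field"))
  spacing <- diff(stress$x[1:2])
  if (mode == "scalar") {
    s <- stress$avg_normal
    if (stats::var(as.vector(s), na.rm = TRUE) == 0)
      stop_data("zero-variance stress field: correlation undefined")
    z <- list(s - mean(s, na.rm = TRUE))
  } else {
    th <- stress$theta
    w1 <- stress$avg_normal * cos(2 * th)
    w2 <- stress$avg_normal * sin(2 * th)
    # isotropic nodes have undefined orientation: zero-weight descriptor
    w1[is.na(th)] <- 0; w2[is.na(th)] <- 0
    z <- list(w1 - mean(w1, na.rm = TRUE), w2 - mean(w2, na.rm = TRUE))
    if (all(abs(z[[1]]) < 1e-300) && all(abs(z[[2]]) < 1e-300))
      stop_data("zero-variance nematic descriptor: correlation undefined")
  }
  b <- binned_pair_correlation(z, spacing)
  correlation_curve(b$r, b$C, b$n_pairs, threshold)
}

#' Threshold-crossing correlation length of a correlation curve
#'
#' The separation at which the autocorrelation first falls below
#' `threshold` (default 0.01), located by linear interpolation between the
#' bracketing bins.  When the curve never reaches the threshold within the
#' field of view the length is undefined and `NA` is returned with attribute
#' `"censored_at"` set to the maximum separation (right-censoring forced by
#' the finite field of view).
#'
#' @param curve a [correlation_curve].
#' @param threshold crossing level.
#' @return length in um, possibly `NA` with attribute `"censored_at"`.
#' @export
correlation_length <- function(curve, threshold = 0.01) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(curve$r) < 2) stop_data("curve needs at least 2 bins")
  len <- crossing_length(curve$r, curve$C, threshold)
  if (is.na(len)) attr(len, "censored_at") <- max(curve$r)
  len
}

#' Sheet migration speed from a movie
#'
#' Two estimators of monolayer sheet speed along the migration axis (x):
#' \describe{
#'   \item{front-edge}{mean advance of the monolayer boundary per unit
#'     time.  Needs a per-frame monolayer mask (supplied, or computed by
#'     intensity thresholding).  The front position of a frame is the mean
#'     over image rows of the largest x covered by the mask.}
#'   \item{piv-mean}{mean axial PIV velocity over the sheet.}
#' }
#'
#' @param movie list of frames (numeric matrices) or, for
#'   `method = "front-edge"` with `masks` supplied, `NULL`.
#' @param method `"front-edge"` or `"piv-mean"`.
#' @param dt frame interval, minutes.
#' @param px_size pixel calibration, um/px.
#' @param masks optional list of logical matrices (monolayer masks).
#' @param mask_threshold relative intensity threshold used to derive masks
#'   from the frames when none are given.
#' @param window_px PIV window for `"piv-mean"`.
#' @return object of class `front_profile`: `time_hr`, `front_um` (front-edge
#'   method), `speed_um_hr` (overall mean speed), `speed_series` (per
#'   interval, um/hr).
#' @export
sheet_speed <- function(movie, method = c("front-edge", "piv-mean"), dt = 10,
                        px_size = 1, masks = NULL, mask_threshold = 0.5,
                        window_px = 32L) {
  method <- match.arg(method)
  if (method == "front-edge") {
    if (is.null(masks)) {
      if (is.null(movie) || length(movie) < 2) stop_data("need >= 2 frames")
      masks <- lapply(movie, function(fr) {
        thr <- min(fr) + mask_threshold * (max(fr) - min(fr))
        fr >= thr
      })
    }
    if (length(masks) < 2) stop_data("need >= 2 frames")
    front <- vapply(masks, function(m) {
      if (!any(m)) stop_data("empty monolayer mask")
      rows <- apply(m, 2, function(col) if (any(col)) max(which(col)) else NA_real_)
      (mean(rows, na.rm = TRUE) - 1) * px_size
    }, numeric(1))
    tt <- (seq_along(masks) - 1) * dt / 60
    series <- diff(front) / diff(tt)
  } else {
    if (is.null(movie) || length(movie) < 2) stop_data("need >= 2 frames")
    fields <- piv_movie(movie, window_px = window_px, dt = dt,
                        px_size = px_size)
    series <- vapply(seq_along(fields), function(t) {
      f <- fields[[t]]
      sel <- !is.na(f$u)
      if (!is.null(masks)) {
        # keep nodes inside the monolayer on both frames of the pair
        m <- masks[[t]] & masks[[t + 1]]
        ix <- pmin(pmax(round(f$x / px_size) + 1, 1), nrow(m))
        iy <- pmin(pmax(round(f$y / px_size) + 1, 1), ncol(m))
        sel <- sel & m[ix, iy]
      }
      if (!any(sel)) stop_data("no valid nodes inside the monolayer mask")
      mean(f$u[sel])
    }, numeric(1))
    tt <- (seq_along(movie) - 1) * dt / 60
    front <- c(0, cumsum(series * diff(tt)))
  }
  structure(list(time_hr = tt, front_um = front,
                 speed_um_hr = mean(series), speed_series = series,
                 method = method),
            class = "front_profile")
}

#' @export
print.front_profile <- function(x, ...) {
  cat(sprintf("<front_profile> %d time points over %.3g hr (%s)\n",
              length(x$time_hr), diff(range(x$time_hr)), x$method))
  cat(sprintf("  mean sheet speed %.4g um/hr\n", x$speed_um_hr))
  invisible(x)
}

#' Change in migration speed around a treatment switch
#'
#' `delta_v = mean speed after t_switch - mean speed before t_switch`,
#' the speed-change readout used for acute perturbations such as
#' E-cadherin-blocking antibody addition.
#'
#' @param profile a `front_profile`.
#' @param t_switch switch time, hours, strictly inside the observed range
#'   with at least 2 intervals on each side.
#' @return `delta_v` in um/hr, with per-phase means as attributes.
#' @export
delta_speed <- function(profile, t_switch) {
  stopifnot(inherits(profile, "front_profile"))
  tt <- profile$time_hr
  if (t_switch <= min(tt) || t_switch >= max(tt))
    stop_invalid("t_switch must lie strictly inside the time range")
  mid <- (tt[-1] + tt[-length(tt)]) / 2   # interval midpoints
  pre <- profile$speed_series[mid < t_switch]
  post <- profile$speed_series[mid >= t_switch]
  if (length(pre) < 2 || length(post) < 2)
    stop_invalid("need at least 2 intervals on each side of t_switch")
  dv <- mean(post) - mean(pre)
  attr(dv, "pre") <- mean(pre)
  attr(dv, "post") <- mean(post)
  dv
}
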