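#' Particle image velocimetry by windowed normalized cross-correlation
#'
#' Each image is tiled into `window_px` square interrogation windows (grid
#' step `window_px * (1 - overlap)`); per window the displacement is the
#' argmax of the normalized cross-correlation between the mean-subtracted
#' window of `image_a` and the locally normalized search region of `image_b`,
#' refined to sub-pixel accuracy by a 3-point Gaussian peak fit in each axis.
#' The vector is assigned to the centre of the window.  The search is limited
#' to `+/- window_px / 2`; larger displacements require a coarser window
#' (multi-pass PIV is out of scope).
#'
#' When the correlation peak is a perfect match (coefficient 1 to numerical
#' precision, as for a noise-free integer translation) the integer lag is
#' returned unrefined, so pure integer shifts are recovered exactly.
#'
#' Windows with (near) zero intensity variance carry no signal and are
#' flagged invalid (`NA` components, quality `NA`).
#'
#' @param image_a,image_b numeric matrices of identical shape.
#' @param window_px interrogation window size, px (>= 8).
#' @param overlap window overlap fraction in `[0, 0.95]` (default 0.5).
#' @param dt frame interval, minutes.  When given (with `px_size`) the field
#'   is returned as velocity in um/hr, otherwise as displacement in px.
#' @param px_size pixel calibration, um/px (default 1).
#' @param search_px half-width of the displacement search, px.
#' @return a [vector_field] (units `"um/hr"` if `dt` given, else `"px"`),
#'   with per-node `quality` = correlation peak coefficient clamped to
#'   `[0, 1]`.
#' @export
compute_piv <- function(image_a, image_b, window_px = 32L, overlap = 0.5,
                        dt = NULL, px_size = 1, search_px = NULL) {
  if (!all(dim(image_a) == dim(image_b)))
    stop_invalid("images must have the same shape")
  w <- as.integer(window_px)
  if (w < 8) stop_invalid("window_px must be >= 8")
  n1 <- nrow(image_a); n2 <- ncol(image_a)
  if (w > n1 || w > n2) stop_invalid("window larger than image")
  if (overlap < 0 || overlap > 0.95) stop_invalid("overlap must be in [0, 0.95]")
  s <- as.integer(search_px %||% (w %/% 2L))
  # every window keeps the full +/- s search range inside the image, so no
  # vector is biased by an unreachable displacement sign at the borders
  s <- min(s, (n1 - w) %/% 2L, (n2 - w) %/% 2L)
  step <- max(1L, round(w * (1 - overlap)))
  gx <- seq(1L + s, n1 - w - s + 1L, by = step)
  gy <- seq(1L + s, n2 - w - s + 1L, by = step)
  U <- V <- Q <- matrix(NA_real_, length(gx), length(gy))
  scale_a <- stats::sd(as.vector(image_a))
  for (ia in seq_along(gx)) {
    i0 <- gx[ia]; i1 <- i0 + w - 1L
    sl <- s; sr <- s
    for (ja in seq_along(gy)) {
      j0 <- gy[ja]; j1 <- j0 + w - 1L
      su <- s; sd_ <- s
      A <- image_a[i0:i1, j0:j1]
      A <- A - mean(A)
      ssA <- sum(A^2)
      if (ssA < (1e-9 * scale_a * w)^2 || ssA == 0) next   # flat window
      B <- image_b[(i0 - sl):(i1 + sr), (j0 - su):(j1 + sd_)]
      m1 <- nrow(B); m2 <- ncol(B)
      Ap <- matrix(0, m1, m2)
      Ap[(sl + 1):(sl + w), (su + 1):(su + w)] <- A
      S <- ifft2_real(Conj(fft2(Ap)) * fft2(B))
      dxs <- (-sl):sr; dys <- (-su):sd_
      S <- S[((dxs %% m1) + 1), ((dys %% m2) + 1), drop = FALSE]
      # local sums of B and B^2 over each candidate w x w block
      int2 <- function(M) {
        cs <- apply(M, 2, cumsum)
        cs <- t(apply(cs, 1, cumsum))
        rbind(0, cbind(0, cs))
      }
      IB <- int2(B); IB2 <- int2(B^2)
      r0 <- sl + dxs + 1L; r1 <- r0 + w - 1L
      c0 <- su + dys + 1L; c1 <- c0 + w - 1L
      rect <- function(I) I[r1 + 1L, c1 + 1L, drop = FALSE] -
        I[r0, c1 + 1L, drop = FALSE] - I[r1 + 1L, c0, drop = FALSE] +
        I[r0, c0, drop = FALSE]
      sb <- rect(IB); sb2 <- rect(IB2)
      varB <- sb2 - sb^2 / (w * w)
      varB[varB < 0] <- 0
      den <- sqrt(ssA * varB)
      ncc <- ifelse(den > 0, S / den, -Inf)
      pk <- arrayInd(which.max(ncc), dim(ncc))
      pi_ <- pk[1]; pj <- pk[2]
      c0v <- ncc[pi_, pj]
      if (!is.finite(c0v)) next
      dx <- dxs[pi_]; dy <- dys[pj]
      if (c0v < 1 - 1e-9) {  # refine unless the match is exact
        if (pi_ > 1 && pi_ < length(dxs))
          dx <- dx + peak_offset_1d(ncc[pi_ - 1, pj], c0v, ncc[pi_ + 1, pj])
        if (pj > 1 && pj < length(dys))
          dy <- dy + peak_offset_1d(ncc[pi_, pj - 1], c0v, ncc[pi_, pj + 1])
      }
      U[ia, ja] <- dx; V[ia, ja] <- dy
      Q[ia, ja] <- min(max(c0v, 0), 1)
    }
  }
  xs <- ((gx + (w - 1) / 2) - 1) * px_size
  ys <- ((gy + (w - 1) / 2) - 1) * px_size
  if (!is.null(dt)) {
    if (dt <= 0) stop_invalid("dt must be > 0")
    f <- px_size * 60 / dt   # px/frame -> um/hr
    vector_field(xs, ys, U * f, V * f, units = "um/hr", px_size = px_size,
                 dt = dt, quality = Q)
  } else {
    vector_field(xs, ys, U, V, units = "px", px_size = px_size, quality = Q)
  }
}

## 3-point sub-pixel peak offset: Gaussian fit if all three values positive,
## parabolic fallback otherwise; clamped to half a pixel.
peak_offset_1d <- function(cm, c0, cp) {
  off <- if (cm > 0 && c0 > 0 && cp > 0 && (cm != c0 || cp != c0)) {
    lm_ <- log(cm); l0 <- log(c0); lp <- log(cp)
    den <- lm_ - 2 * l0 + lp
    if (den < 0) 0.5 * (lm_ - lp) / den else 0
  } else {
    den <- cm - 2 * c0 + cp
    if (den < 0) 0.5 * (cm - cp) / den else 0
  }
  min(max(off, -0.5), 0.5)
}

#' PIV over a movie (consecutive frame pairs)
#'
#' @param stack list of frames (numeric matrices), >= 2.
#' @param window_px,overlap,px_size see [compute_piv].
#' @param dt frame interval, minutes (default 10).
#' @return list of [vector_field]s, one per consecutive pair, on a common
#'   grid.
#' @export
piv_movie <- function(stack, window_px = 32L, overlap = 0.5, dt = 10,
                      px_size = 1) {
  if (length(stack) < 2) stop_data("need at least 2 frames")
  lapply(seq_len(length(stack) - 1L), function(t)
    compute_piv(stack[[t]], stack[[t + 1]], window_px = window_px,
                overlap = overlap, dt = dt, px_size = px_size))
}

#' Gaussian smoothing of a vector field
#'
#' Component-wise Gaussian filter on the field grid, used to suppress
#' node-to-node PIV jitter before traction inversion (the window
#' cross-correlation responds to the beads actually sampled, so fields
#' carry high-wavenumber estimation noise that the inverse elastic problem
#' would amplify).  `periodic = TRUE` wraps around (appropriate for fields
#' sampled over a full period of a periodic scene); otherwise edges are
#' reflected.
#'
#' @param field a [vector_field].
#' @param sigma_nodes filter standard deviation in grid-node units.
#' @param periodic wrap at the edges instead of reflecting.
#' @return the smoothed [vector_field].
#' @export
smooth_field <- function(field, sigma_nodes = 1, periodic = FALSE) {
  stopifnot(inherits(field, "vector_field"))
  if (sigma_nodes <= 0) return(field)
  f <- if (periodic) function(m) gauss_smooth_periodic(m, sigma_nodes)
       else function(m) gauss_smooth_small(m, sigma_nodes)
  field$u <- f(field$u)
  field$v <- f(field$v)
  field
}

#' Replace outlier vectors by the local median
#'
#' A vector whose deviation from the median of its 8-neighbourhood exceeds
#' `threshold` (Euclidean norm, field units) is replaced by that median;
#' invalid (`NA`) vectors are filled the same way.  The number of
#' replacements is attached as attribute `"n_replaced"`.
#'
#' @param field a [vector_field].
#' @param threshold residual norm threshold in the field's units.
#' @return the filtered [vector_field].
#' @export
replace_outliers <- function(field, threshold) {
  stopifnot(inherits(field, "vector_field"))
  medu <- neighbor_median(field$u)
  medv <- neighbor_median(field$v)
  res <- sqrt((field$u - medu)^2 + (field$v - medv)^2)
  bad <- (is.na(field$u) | (!is.na(res) & res > threshold)) &
    !is.na(medu) & !is.na(medv)
  field$u[bad] <- medu[bad]
  field$v[bad] <- medv[bad]
  attr(field, "n_replaced") <- sum(bad)
  field
}

## median over the 8-neighbourhood (centre excluded), NA-tolerant
neighbor_median <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- matrix(NA_real_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    ii <- max(1, i - 1):min(n1, i + 1)
    jj <- max(1, j - 1):min(n2, j + 1)
    v <- m[ii, jj]
    v <- v[-((which(ii == i)) + (which(jj == j) - 1) * length(ii))]
    if (any(!is.na(v))) out[i, j] <- stats::median(v, na.rm = TRUE)
  }
  out
}
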