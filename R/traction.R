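#' Elastic substrate description
#'
#' Linear-elastic, semi-infinite (Boussinesq half-space) substrate.  The
#' hydrogels used for traction microscopy are thick relative to the decay
#' depth of surface displacements, so finite thickness is neglected.
#' Polyacrylamide is nearly incompressible, hence the default Poisson ratio
#' of 0.5; it is configurable.
#'
#' @param youngs_modulus Young's modulus, Pa (e.g. 11e3, 23e3, 55e3, 90e3).
#' @param poisson_ratio Poisson ratio in `[0, 0.5]`.
#' @return object of class `elastic_substrate`.
#' @export
elastic_substrate <- function(youngs_modulus, poisson_ratio = 0.5) {
  if (youngs_modulus <= 0) stop_invalid("youngs_modulus must be > 0")
  if (poisson_ratio < 0 || poisson_ratio > 0.5)
    stop_invalid("poisson_ratio must be in [0, 0.5]")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "elastic_substrate")
}

## Per-mode tangential Green's tensor of the elastic half-space surface,
## G(k) = 2(1+nu)/(E k^3) [ ((1-nu)k^2 + nu ky^2, -nu kx ky),
##                          (-nu kx ky, (1-nu)k^2 + nu kx^2) ].
## Returns the four component matrices over the wavevector grid (g12 = g21).
greens_tensor <- function(K1, K2, substrate) {
  E <- substrate$youngs_modulus; nu <- substrate$poisson_ratio
  k2 <- K1^2 + K2^2
  k <- sqrt(k2)
  pref <- 2 * (1 + nu) / (E * k^3)
  g11 <- pref * ((1 - nu) * k2 + nu * K2^2)
  g22 <- pref * ((1 - nu) * k2 + nu * K1^2)
  g12 <- pref * (-nu * K1 * K2)
  g11[k2 == 0] <- 0; g22[k2 == 0] <- 0; g12[k2 == 0] <- 0
  list(g11 = g11, g12 = g12, g22 = g22)
}

#' Surface displacement of an elastic half-space under a traction field
#'
#' Forward Boussinesq operator: per Fourier mode `u(k) = G(k) t(k)` with the
#' standard tangential half-space Green's tensor; the `k = 0` mode is zero
#' (the traction must be zero-mean for half-space equilibrium).
#'
#' @param traction a `traction_field` (Pa) on a regular grid.
#' @param substrate an [elastic_substrate].
#' @return a [vector_field] of surface displacements, um.
#' @export
forward_boussinesq <- function(traction, substrate) {
  stopifnot(inherits(traction, "vector_field"),
            inherits(substrate, "elastic_substrate"))
  tx <- traction$u; ty <- traction$v
  tscale <- max(abs(tx), abs(ty))
  if (tscale > 0 &&
      max(abs(mean(tx)), abs(mean(ty))) > 1e-8 * tscale)
    stop_invalid("traction must be zero-mean (half-space equilibrium)")
  d <- grid_spacing(traction)
  n1 <- nrow(tx); n2 <- ncol(tx)
  K1 <- matrix(fft_wavenumbers(n1, d), n1, n2)
  K2 <- matrix(fft_wavenumbers(n2, d), n1, n2, byrow = TRUE)
  G <- greens_tensor(K1, K2, substrate)
  Tx <- fft2(tx); Ty <- fft2(ty)
  Ux <- G$g11 * Tx + G$g12 * Ty
  Uy <- G$g12 * Tx + G$g22 * Ty
  vector_field(traction$x, traction$y, ifft2_real(Ux), ifft2_real(Uy),
               units = "um")
}

#' Regularized Fourier-transform traction cytometry
#'
#' Inverts a surface displacement field to tractions by per-mode Tikhonov
#' regularization, `t(k) = (G'G + lambda^2 s0^2 I)^-1 G' u(k)`, where `s0 =
#' 2(1+nu)/(E k1)` (the Green's-function magnitude at the fundamental mode
#' `k1`) makes `reg_lambda` dimensionless.  The `k = 0` traction is set to
#' zero (zero-mode suppressed).  With `reg_lambda = 0` this is the exact
#' inverse of [forward_boussinesq] on the same periodic grid.
#'
#' By default the displacement field is zero-padded to twice its extent
#' before the FFT to suppress periodic wrap-around (the substrate is a
#' half-space, not a torus); set `pad = FALSE` for fields that are genuinely
#' periodic, e.g. synthetic scenes.
#'
#' @param displacement a [vector_field] of surface displacements (um).
#' @param substrate an [elastic_substrate].
#' @param reg_lambda dimensionless Tikhonov parameter (>= 0), or `"auto"` to
#'   pick it by the L-curve corner (see [lcurve_lambda]).
#' @param pad zero-pad to twice the grid before inversion (default `TRUE`).
#' @return a `traction_field` (Pa) with the regularization parameter used.
#' @export
fttc <- function(displacement, substrate, reg_lambda = 0, pad = TRUE) {
  stopifnot(inherits(displacement, "vector_field"),
            inherits(substrate, "elastic_substrate"))
  if (displacement$units == "px") displacement <- convert_units(displacement, "um")
  if (identical(reg_lambda, "auto"))
    reg_lambda <- lcurve_lambda(displacement, substrate, pad = pad)
  if (!is.numeric(reg_lambda) || reg_lambda < 0)
    stop_invalid("reg_lambda must be >= 0 or \"auto\"")
  tr <- fttc_engine(displacement$u, displacement$v, grid_spacing(displacement),
                    substrate, reg_lambda, pad)
  traction_field(displacement$x, displacement$y, tr$tx, tr$ty,
                 reg_lambda = reg_lambda)
}

fttc_engine <- function(ux, uy, d, substrate, reg_lambda, pad) {
  n1 <- nrow(ux); n2 <- ncol(ux)
  if (pad) {
    m1 <- 2L * n1; m2 <- 2L * n2
    pux <- matrix(0, m1, m2); puy <- matrix(0, m1, m2)
    pux[1:n1, 1:n2] <- ux; puy[1:n1, 1:n2] <- uy
  } else {
    m1 <- n1; m2 <- n2; pux <- ux; puy <- uy
  }
  K1 <- matrix(fft_wavenumbers(m1, d), m1, m2)
  K2 <- matrix(fft_wavenumbers(m2, d), m1, m2, byrow = TRUE)
  G <- greens_tensor(K1, K2, substrate)
  s0 <- 2 * (1 + substrate$poisson_ratio) /
    (substrate$youngs_modulus * (2 * pi / (max(m1, m2) * d)))
  l2 <- (reg_lambda * s0)^2
  Ux <- fft2(pux); Uy <- fft2(puy)
  # (G'G + l2 I)^-1 G' u, G symmetric 2x2 per mode
  a <- G$g11^2 + G$g12^2 + l2
  b <- G$g12 * (G$g11 + G$g22)
  c_ <- G$g22^2 + G$g12^2 + l2
  det <- a * c_ - b^2
  rx <- G$g11 * Ux + G$g12 * Uy
  ry <- G$g12 * Ux + G$g22 * Uy
  Tx <- (c_ * rx - b * ry) / det
  Ty <- (a * ry - b * rx) / det
  Tx[det == 0 | (K1 == 0 & K2 == 0)] <- 0
  Ty[det == 0 | (K1 == 0 & K2 == 0)] <- 0
  tx <- ifft2_real(Tx); ty <- ifft2_real(Ty)
  tx <- tx[1:n1, 1:n2] ; ty <- ty[1:n1, 1:n2]
  # suppress any residual mean over the cropped region
  list(tx = tx - mean(tx), ty = ty - mean(ty))
}

#' L-curve choice of the FTTC regularization parameter
#'
#' Sweeps `reg_lambda` over a log grid, records residual norm
#' `||G t - u||` and solution norm `||t||`, and returns the parameter at the
#' corner (maximum curvature of the log-log L-curve).
#'
#' @param displacement,substrate,pad as in [fttc].
#' @param lambdas candidate dimensionless parameters (log-spaced default).
#' @return the selected `reg_lambda`, with the sweep as attribute
#'   `"lcurve"`.
#' @export
lcurve_lambda <- function(displacement, substrate,
                          lambdas = 10^seq(-3.5, 0.5, length.out = 41),
                          pad = TRUE) {
  ux <- displacement$u; uy <- displacement$v
  d <- grid_spacing(displacement)
  rho <- eta <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    tr <- fttc_engine(ux, uy, d, substrate, lambdas[i], pad)
    tf <- traction_field(displacement$x, displacement$y, tr$tx, tr$ty)
    ub <- forward_boussinesq(tf, substrate)
    rho[i] <- sqrt(sum((ub$u - ux)^2 + (ub$v - uy)^2))
    eta[i] <- sqrt(sum(tr$tx^2 + tr$ty^2))
  }
  lr <- log(rho); le <- log(eta)
  # curvature of the parametric curve (lr, le)(log lambda); segments where
  # the curve barely moves (flat small-lambda floor) carry no corner
  # information and only produce numerical-noise curvature, so they are
  # excluded by a minimum-speed rule
  h <- diff(log(lambdas))[1]
  d1r <- c(NA, diff(lr, lag = 2) / (2 * h), NA)
  d1e <- c(NA, diff(le, lag = 2) / (2 * h), NA)
  d2r <- c(NA, diff(diff(lr)) / h^2, NA)
  d2e <- c(NA, diff(diff(le)) / h^2, NA)
  speed <- sqrt(d1r^2 + d1e^2)
  kappa <- (d1r * d2e - d2r * d1e) / speed^3
  kappa[!is.finite(kappa) | speed < 0.02] <- NA
  if (all(is.na(kappa))) {
    best <- ceiling(length(lambdas) / 2)
  } else {
    best <- which.max(abs(kappa))
  }
  lam <- lambdas[best]
  attr(lam, "lcurve") <- data.frame(lambda = lambdas, rho = rho, eta = eta,
                                    curvature = kappa)
  lam
}

#' Bead displacement field from a stressed/relaxed image pair
#'
#' Runs PIV on the pair after estimating (and removing) rigid stage drift by
#' whole-image cross-correlation with sub-pixel refinement.  The drift vector
#' is attached as attribute `"drift_px"`.
#'
#' @param stressed_img,relaxed_img bead images (numeric matrices).
#' @param window_px PIV window, px.
#' @param px_size pixel calibration, um/px.
#' @param overlap PIV window overlap fraction.
#' @return a [vector_field] of substrate displacements in um (relaxed ->
#'   stressed).
#' @export
displacement_from_beads <- function(stressed_img, relaxed_img, window_px = 32L,
                                    px_size = 1, overlap = 0.5) {
  drift <- estimate_drift(relaxed_img, stressed_img)
  fld <- compute_piv(relaxed_img, stressed_img, window_px = window_px,
                     overlap = overlap, px_size = px_size)
  fld$u <- fld$u - drift[1]
  fld$v <- fld$v - drift[2]
  fld <- convert_units(fld, "um")
  attr(fld, "drift_px") <- drift
  fld
}

## Rigid shift between two images by phase correlation (unit-normalized
## cross-power spectrum): the delta-like peak locates a rigid translation
## and is insensitive to smooth elastic deformation, which is exactly what
## drift correction must not absorb.  Sub-pixel refinement by the 3-point
## parabolic fit on the correlation surface.
estimate_drift <- function(a, b, max_shift = 32L) {
  n1 <- nrow(a); n2 <- ncol(a)
  FA <- stats::fft(a - mean(a)); FB <- stats::fft(b - mean(b))
  R <- FB * Conj(FA)
  m <- Mod(R)
  if (max(m) == 0) stop_data("drift estimation failed: blank images")
  R <- R / pmax(m, 1e-12 * max(m))
  r <- Re(stats::fft(R, inverse = TRUE)) / length(R)
  # restrict to |shift| <= max_shift (wrapped lags)
  ok1 <- c(0:(n1 - 1)) ; ok1 <- pmin(ok1, n1 - ok1) <= max_shift
  ok2 <- c(0:(n2 - 1)) ; ok2 <- pmin(ok2, n2 - ok2) <= max_shift
  r[!ok1, ] <- -Inf; r[, !ok2] <- -Inf
  if (max(r) < 0.01)
    stop_data("drift estimation failed: no correlation peak")
  pk <- arrayInd(which.max(r), dim(r))
  wrap <- function(i, n) { d <- i - 1L; if (d > n / 2) d - n else d }
  dx <- wrap(pk[1], n1); dy <- wrap(pk[2], n2)
  at <- function(di, dj) r[((pk[1] - 1 + di) %% n1) + 1,
                           ((pk[2] - 1 + dj) %% n2) + 1]
  if (at(0, 0) < 1 - 1e-9) {
    if (is.finite(at(-1, 0)) && is.finite(at(1, 0)))
      dx <- dx + peak_offset_1d(at(-1, 0), at(0, 0), at(1, 0))
    if (is.finite(at(0, -1)) && is.finite(at(0, 1)))
      dy <- dy + peak_offset_1d(at(0, -1), at(0, 0), at(0, 1))
  }
  c(dx, dy)
}

#' Mean traction magnitude over a region
#'
#' @param traction a `traction_field` (Pa).
#' @param mask optional logical matrix selecting nodes (default: all).
#' @return list with `mean_pa` and `rms_pa` of `|t|` over the mask.
#' @export
traction_summary <- function(traction, mask = NULL) {
  stopifnot(inherits(traction, "vector_field"))
  mag <- sqrt(traction$u^2 + traction$v^2)
  if (is.null(mask)) mask <- !is.na(mag)
  if (!any(mask)) stop_data("empty mask")
  list(mean_pa = mean(mag[mask], na.rm = TRUE),
       rms_pa = sqrt(mean(mag[mask]^2, na.rm = TRUE)))
}
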