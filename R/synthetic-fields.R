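#' Specification of a synthetic monolayer velocity field
#'
#' Describes a velocity field as a uniform drift plus lateral fluctuations of
#' tunable spatial correlation.  Fluctuations are white Gaussian noise
#' convolved with an isotropic Gaussian kernel of scale `kernel_scale`, then
#' rescaled to `fluctuation_sd`; their normalized spatial autocorrelation is
#' `exp(-r^2 / (4 * kernel_scale^2))` in expectation, so the C(r) = 0.01
#' crossing sits at `2 * kernel_scale * sqrt(log(100))` (about 4.29 times the
#' kernel scale).
#'
#' @param grid_shape integer vector of nodes per axis (length 1 or 2).
#' @param node_spacing grid spacing, um.
#' @param drift_speed mean migration speed, um/hr.
#' @param drift_direction planar direction of migration (normalized
#'   internally).
#' @param fluctuation_sd standard deviation of the fluctuating part, um/hr.
#' @param kernel_scale Gaussian smoothing scale of the fluctuations, um.
#' @param seed integer seed; identical spec and seed give identical fields.
#' @return object of class `field_spec`.
#' @export
field_spec <- function(grid_shape, node_spacing, drift_speed = 0,
                       drift_direction = c(1, 0), fluctuation_sd = 0,
                       kernel_scale = 0, seed = 1L) {
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 2)
  if (node_spacing <= 0) stop_invalid("node_spacing must be > 0")
  if (fluctuation_sd < 0) stop_invalid("fluctuation_sd must be >= 0")
  if (kernel_scale < 0) stop_invalid("kernel_scale must be >= 0")
  nrm <- sqrt(sum(drift_direction^2))
  if (nrm == 0) stop_invalid("drift_direction must be nonzero")
  structure(list(grid_shape = as.integer(grid_shape),
                 node_spacing = node_spacing, drift_speed = drift_speed,
                 drift_direction = drift_direction / nrm,
                 fluctuation_sd = fluctuation_sd, kernel_scale = kernel_scale,
                 seed = as.integer(seed)),
            class = "field_spec")
}

#' Generate a synthetic velocity field (drift + correlated fluctuations)
#'
#' @param spec a [field_spec].
#' @param n_frames number of independent realizations; with `n_frames > 1` a
#'   list of fields is returned (fluctuations independent across frames, drift
#'   shared).
#' @return a [vector_field] in um/hr (or a list of them), with the generating
#'   spec attached as attribute `"spec"`.
#' @export
gen_velocity_field <- function(spec, n_frames = 1L) {
  stopifnot(inherits(spec, "field_spec"))
  n1 <- spec$grid_shape[1]; n2 <- spec$grid_shape[2]
  domain <- min(n1, n2) * spec$node_spacing
  if (spec$kernel_scale > domain / 4)
    warning("kernel_scale exceeds a quarter of the domain; ",
            "correlation length will not be resolvable")
  sigma_nodes <- spec$kernel_scale / spec$node_spacing
  one <- function(k) {
    with_seed(derive_seed(spec$seed, paste0("velocity_field/", k)), {
      comp <- lapply(1:2, function(i) {
        w <- matrix(stats::rnorm(n1 * n2), n1, n2)
        s <- gauss_smooth_periodic(w, sigma_nodes)
        if (spec$fluctuation_sd > 0) {
          sdv <- stats::sd(as.vector(s))
          if (sdv > 0) s <- s * (spec$fluctuation_sd / sdv) else s[] <- 0
        } else s[] <- 0
        s
      })
      u <- comp[[1]] + spec$drift_speed * spec$drift_direction[1]
      v <- comp[[2]] + spec$drift_speed * spec$drift_direction[2]
      f <- vector_field(x = (seq_len(n1) - 1) * spec$node_spacing,
                        y = (seq_len(n2) - 1) * spec$node_spacing,
                        u = u, v = v, units = "um/hr")
      attr(f, "spec") <- spec
      f
    })
  }
  if (n_frames == 1L) one(1L) else lapply(seq_len(n_frames), one)
}

#' Specification of a synthetic equilibrium stress/traction scene
#'
#' A smooth in-plane stress tensor field built from sinusoidal modes, together
#' with the traction field that balances it.  Modes are either direct stress
#' patterns (`"xx"`, `"yy"`, `"xy"`, `"iso"`) or elastically compatible
#' displacement modes (`"compression"`, `"shear"`) of a plane-stress sheet
#' with Poisson ratio `sheet_poisson`; compatible modes are what monolayer
#' stress microscopy can recover exactly, direct patterns are used for
#' analytic divergence checks.  Wavevectors are snapped to the periodic grid.
#'
#' @param grid_shape nodes per axis (length 1 or 2).
#' @param node_spacing grid spacing, um.
#' @param stress_modes list of modes, each
#'   `list(amplitude = <N/m>, wavevector = c(kx, ky) [1/um], pattern = <chr>,
#'   phase = <rad>)`; `NULL` to draw `n_modes` random compatible modes.
#' @param n_modes number of random modes when `stress_modes` is `NULL`.
#' @param amplitude r.m.s. amplitude for random modes, N/m.
#' @param wavelength_range range of wavelengths for random modes, um.
#' @param sheet_poisson effective Poisson ratio of the monolayer sheet used by
#'   the compatible patterns.
#' @param substrate_modulus substrate Young's modulus, Pa.
#' @param substrate_poisson substrate Poisson ratio.
#' @param envelope `"none"` (default) for the plain periodic scene, or
#'   `"hann"` to window the stress by a separable raised-cosine
#'   `(1 - cos(2 pi x / L)) (1 - cos(2 pi y / L)) / 4`, which vanishes at
#'   the view edges so tractions decay to zero inside the field of view, as
#'   they do around a cell colony.  The window is a finite Fourier series,
#'   so the windowed scene stays exactly band-limited and the traction is
#'   the exact analytic divergence of the windowed stress.
#' @param seed integer seed.
#' @return object of class `stress_scene_spec`.
#' @export
stress_scene_spec <- function(grid_shape, node_spacing, stress_modes = NULL,
                              n_modes = 4L, amplitude = 1e-3,
                              wavelength_range = NULL,
                              sheet_poisson = 0.5,
                              substrate_modulus = 23e3,
                              substrate_poisson = 0.5,
                              envelope = c("none", "hann"), seed = 1L) {
  envelope <- match.arg(envelope)
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 2)
  if (node_spacing <= 0) stop_invalid("node_spacing must be > 0")
  if (substrate_modulus <= 0) stop_invalid("substrate_modulus must be > 0")
  if (substrate_poisson < 0 || substrate_poisson > 0.5)
    stop_invalid("substrate_poisson must be in [0, 0.5]")
  if (is.null(wavelength_range))
    wavelength_range <- c(0.2, 0.5) * min(grid_shape) * node_spacing
  structure(list(grid_shape = as.integer(grid_shape),
                 node_spacing = node_spacing, stress_modes = stress_modes,
                 n_modes = as.integer(n_modes), amplitude = amplitude,
                 wavelength_range = wavelength_range,
                 sheet_poisson = sheet_poisson,
                 substrate_modulus = substrate_modulus,
                 substrate_poisson = substrate_poisson,
                 envelope = envelope,
                 seed = as.integer(seed)),
            class = "stress_scene_spec")
}

# snap a wavevector onto the periodic reciprocal lattice of the grid
snap_wavevector <- function(k, n, d) {
  L <- n * d
  m <- round(k * L / (2 * pi))
  2 * pi * m / L
}

# constant tensor M for a unit-amplitude mode pattern
mode_tensor <- function(pattern, khat, nu) {
  kx <- khat[1]; ky <- khat[2]
  kp <- c(-ky, kx)
  switch(pattern,
    xx  = matrix(c(1, 0, 0, 0), 2, 2),
    yy  = matrix(c(0, 0, 0, 1), 2, 2),
    xy  = matrix(c(0, 1, 1, 0), 2, 2),
    iso = diag(2),
    compression = outer(khat, khat) + nu * outer(kp, kp),
    shear = outer(khat, kp) + outer(kp, khat),
    stop_invalid("unknown mode pattern: ", pattern))
}

#' Generate a balanced stress/traction scene
#'
#' Builds the stress tensor field from the scene's modes and the traction
#' field as the analytic divergence of that stress
#' (`t_i = sum_j d sigma_ij / d x_j`), so the pair satisfies the discrete
#' force balance of the periodic grid to machine precision.  Sign convention:
#' `t` is the traction exerted by the substrate on the monolayer.
#'
#' @param spec a [stress_scene_spec].
#' @return list with elements `stress` (a [stress_field]) and `traction`
#'   (a `traction_field`, Pa -- here interpreted as N/m per um, i.e. the
#'   divergence of a line stress; see Details).
#' @details With stress in N/m and lengths in um, the balancing traction has
#'   units N/m/um = 1e6 N/m^2; components are stored in Pa (1 N/m per um =
#'   1e6 Pa).
#' @export
gen_equilibrium_scene <- function(spec) {
  stopifnot(inherits(spec, "stress_scene_spec"))
  n1 <- spec$grid_shape[1]; n2 <- spec$grid_shape[2]
  d <- spec$node_spacing
  modes <- spec$stress_modes
  if (is.null(modes)) {
    modes <- with_seed(derive_seed(spec$seed, "equilibrium_scene"), {
      lapply(seq_len(spec$n_modes), function(i) {
        wl <- stats::runif(1, spec$wavelength_range[1], spec$wavelength_range[2])
        ang <- stats::runif(1, 0, 2 * pi)
        list(amplitude = spec$amplitude * sample(c(-1, 1), 1),
             wavevector = (2 * pi / wl) * c(cos(ang), sin(ang)),
             pattern = sample(c("compression", "compression", "shear"), 1),
             phase = stats::runif(1, 0, 2 * pi))
      })
    })
  }
  xs <- (seq_len(n1) - 1) * d
  ys <- (seq_len(n2) - 1) * d
  X <- matrix(xs, n1, n2); Y <- matrix(ys, n1, n2, byrow = TRUE)
  sxx <- syy <- sxy <- tx <- ty <- matrix(0, n1, n2)
  for (m in modes) {
    k <- c(snap_wavevector(m$wavevector[1], n1, d),
           snap_wavevector(m$wavevector[2], n2, d))
    kn <- sqrt(sum(k^2))
    khat <- if (kn > 0) k / kn else c(1, 0)
    M <- mode_tensor(m$pattern %||% "compression", khat, spec$sheet_poisson)
    ph <- m$phase %||% 0
    f <- m$amplitude * sin(k[1] * X + k[2] * Y + ph)
    fp <- m$amplitude * cos(k[1] * X + k[2] * Y + ph)   # d/d(k.x)
    sxx <- sxx + f * M[1, 1]; syy <- syy + f * M[2, 2]; sxy <- sxy + f * M[1, 2]
    Mk <- M %*% k   # divergence of sin-mode stress: cos * (M k)
    tx <- tx + fp * Mk[1]
    ty <- ty + fp * Mk[2]
  }
  if (identical(spec$envelope %||% "none", "hann")) {
    # separable raised-cosine window w = hx * hy with h = (1 - cos(2 pi x / L))/2;
    # exactly periodic and band-limited, zero at the view edges.  The
    # balancing traction is div(w sigma) = w div(sigma) + sigma grad(w).
    Lx <- n1 * d; Ly <- n2 * d
    hx <- (1 - cos(2 * pi * X / Lx)) / 2
    hy <- (1 - cos(2 * pi * Y / Ly)) / 2
    W <- hx * hy
    wx <- (pi / Lx) * sin(2 * pi * X / Lx) * hy
    wy <- (pi / Ly) * sin(2 * pi * Y / Ly) * hx
    tx <- W * tx + sxx * wx + sxy * wy
    ty <- W * ty + sxy * wx + syy * wy
    sxx <- W * sxx; syy <- W * syy; sxy <- W * sxy
  }
  stress <- stress_field(xs, ys, sxx, syy, sxy)
  # stress N/m, lengths um: divergence is N/m/um = 1e6 Pa
  traction <- traction_field(xs, ys, tx * 1e6, ty * 1e6)
  attr(stress, "spec") <- spec
  attr(traction, "spec") <- spec
  list(stress = stress, traction = traction)
}

#' Traction field container
#'
#' A [vector_field] whose components are traction stresses in Pa, with the
#' regularization parameter used for its recovery (if any).
#' @param x,y node positions (um).
#' @param tx,ty traction components (Pa).
#' @param reg_lambda regularization parameter used in recovery, if any.
#' @return object of classes `traction_field`, `vector_field`.
#' @export
traction_field <- function(x, y, tx, ty, reg_lambda = NA_real_) {
  f <- vector_field(x, y, tx, ty, units = "Pa")
  f$reg_lambda <- reg_lambda
  class(f) <- c("traction_field", class(f))
  f
}

#' Residual of the discrete force balance between stress and traction
#'
#' Computes `||div(sigma) - t|| / ||t||` with the divergence taken by the
#' periodic grid's spectral (Fourier-collocation) derivative, which is the
#' discrete derivative consistent with the sinusoidal scene modes and the
#' spectral MSM solver.
#'
#' @param stress a [stress_field] (N/m).
#' @param traction a `traction_field` (Pa).
#' @return relative residual (dimensionless).
#' @export
balance_residual <- function(stress, traction) {
  d <- diff(stress$x[1:2])
  n1 <- length(stress$x); n2 <- length(stress$y)
  k1 <- fft_wavenumbers(n1, d); k2 <- fft_wavenumbers(n2, d)
  K1 <- matrix(k1, n1, n2); K2 <- matrix(k2, n1, n2, byrow = TRUE)
  ddx <- function(z) ifft2_real(fft2(z) * (1i * K1))
  ddy <- function(z) ifft2_real(fft2(z) * (1i * K2))
  # stress N/m over um -> 1e6 Pa
  rx <- (ddx(stress$sxx) + ddy(stress$sxy)) * 1e6 - traction$u
  ry <- (ddx(stress$sxy) + ddy(stress$syy)) * 1e6 - traction$v
  tn <- sqrt(sum(traction$u^2 + traction$v^2))
  if (tn == 0) return(sqrt(sum(rx^2 + ry^2)))
  sqrt(sum(rx^2 + ry^2)) / tn
}
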