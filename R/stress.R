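#' Monolayer stress microscopy: recover in-plane stress from tractions
#'
#' Solves the two-dimensional force balance
#' `d sigma_xx/dx + d sigma_xy/dy = t_x`,
#' `d sigma_xy/dx + d sigma_yy/dy = t_y`
#' for the in-plane line stress tensor (N/m) of the monolayer, closing the
#' underdetermined balance with the compatibility of a linear plane-stress
#' elastic sheet of Poisson ratio `sheet_poisson` (the effective modulus
#' drops out of the recovered stress).  `t` is the traction exerted by the
#' substrate on the monolayer: the reaction to the traction measured by TFM,
#' i.e. `msm_solve(traction)` on TFM output expects the sign flip to have
#' been applied via `flip_sign = TRUE` (the default), and the flip is
#' recorded in the result.
#'
#' Boundary handling:
#' \describe{
#'   \item{`"periodic"`}{interior-field mode for views fully inside a
#'     confluent monolayer.  Solved spectrally; the mean stress is not
#'     observable from tractions and is fixed to zero (zero-mean gauge), so
#'     only stress variations are meaningful.  The gauge constant (0) is
#'     recorded in the result.}
#'   \item{`"free"`}{all four edges are traction-free monolayer boundaries
#'     (requires a net-balanced traction field).  Solved by second-order
#'     finite differences as a sparse least-squares system.}
#'   \item{length-4 character vector}{per-edge conditions, in the order
#'     `(left, right, bottom, top)` = (x min, x max, y min, y max), each
#'     `"free"` or `"clamped"`; `"clamped"` pins the sheet displacement,
#'     modelling continuation of the monolayer beyond the view.}
#' }
#'
#' @param traction a `traction_field` (Pa) on a regular grid.
#' @param monolayer_mask optional logical matrix; only the full-rectangle
#'   mask is supported (the paper's interior-field use case); any `FALSE`
#'   entries raise an error.
#' @param boundary `"periodic"`, `"free"`, or per-edge conditions (above).
#' @param sheet_poisson effective Poisson ratio of the sheet closure.
#' @param flip_sign flip the sign of the input traction (TFM convention
#'   measures cell-on-substrate traction; the balance needs
#'   substrate-on-cell).
#' @param balance_tol relative tolerance on the net traction for free
#'   boundaries.
#' @return a [stress_field] (N/m) with attributes `"balance_residual"`
#'   (relative residual of the discrete balance) and `"sign_flipped"`.
#' @export
msm_solve <- function(traction, monolayer_mask = NULL,
                      boundary = "periodic", sheet_poisson = 0.5,
                      flip_sign = TRUE, balance_tol = 1e-6) {
  stopifnot(inherits(traction, "vector_field"))
  if (!is.null(monolayer_mask) && !all(monolayer_mask))
    stop_invalid("only the full-rectangle monolayer mask is supported")
  # Pa -> N/m per um
  sgn <- if (flip_sign) -1 else 1
  tx <- sgn * traction$u * 1e-6
  ty <- sgn * traction$v * 1e-6
  d <- grid_spacing(traction)
  periodic <- identical(boundary, "periodic")
  if (!periodic) {
    edges <- if (identical(boundary, "free")) rep("free", 4) else boundary
    if (length(edges) != 4 || !all(edges %in% c("free", "clamped")))
      stop_invalid("boundary must be \"periodic\", \"free\", or 4 edge conditions")
    if (all(edges == "free")) {
      tscale <- max(abs(tx), abs(ty), 1e-300)
      if (max(abs(mean(tx)), abs(mean(ty))) > balance_tol * tscale)
        stop_data("net traction is unbalanced; remove the mean traction ",
                  "before solving with free boundaries")
    }
    res <- msm_solve_fd(tx, ty, d, edges, sheet_poisson)
  } else {
    res <- msm_solve_periodic(tx, ty, d, sheet_poisson)
  }
  out <- stress_field(traction$x, traction$y, res$sxx, res$syy, res$sxy,
                      gauge = if (periodic) 0 else NA_real_)
  attr(out, "balance_residual") <- if (periodic)
    msm_balance_residual(res$sxx, res$syy, res$sxy, tx, ty, d)
  else res$residual
  attr(out, "sign_flipped") <- flip_sign
  out
}

## spectral solve on the periodic grid: per mode A(k) u = -t with
## A = mu k^2 I + (mu + lam) k k', then sigma from u.
msm_solve_periodic <- function(tx, ty, d, nu) {
  n1 <- nrow(tx); n2 <- ncol(tx)
  mu <- 1 / (2 * (1 + nu))          # effective modulus 1
  lam <- nu / (1 - nu^2)
  K1 <- matrix(fft_wavenumbers(n1, d), n1, n2)
  K2 <- matrix(fft_wavenumbers(n2, d), n1, n2, byrow = TRUE)
  k2 <- K1^2 + K2^2
  Tx <- fft2(tx); Ty <- fft2(ty)
  a <- mu * k2 + (mu + lam) * K1^2
  b <- (mu + lam) * K1 * K2
  c_ <- mu * k2 + (mu + lam) * K2^2
  det <- a * c_ - b^2
  det[k2 == 0] <- 1
  Uxk <- -(c_ * Tx - b * Ty) / det
  Uyk <- -(a * Ty - b * Tx) / det
  Uxk[k2 == 0] <- 0; Uyk[k2 == 0] <- 0
  exx <- 1i * K1 * Uxk
  eyy <- 1i * K2 * Uyk
  exy <- 0.5i * (K2 * Uxk + K1 * Uyk)
  c11 <- 1 / (1 - nu^2); c12 <- nu * c11
  list(sxx = ifft2_real(c11 * exx + c12 * eyy),
       syy = ifft2_real(c12 * exx + c11 * eyy),
       sxy = ifft2_real(2 * mu * exy))
}

## Finite-difference plane-stress solve on a rectangle with per-edge
## free/clamped conditions.  Collocation: balance equations at interior
## nodes, boundary-condition equations at edge nodes (Dirichlet at clamped
## edges; sigma.n = 0 at free edges, with the two normal conditions at
## free-free corners), giving a square system whose interior balance is
## satisfied to machine precision.  Second-order one-sided stencils at the
## edges keep polynomial displacement solutions (up to quadratic) exact,
## which makes the 1D strip oracle sigma_xx = t0 * x hold to machine
## precision.  An all-free rectangle has a three-dimensional rigid-body
## null space, pinned by three appended mean-motion rows (consistent for
## net-force- and net-torque-free tractions).
msm_solve_fd <- function(tx, ty, d, edges, nu) {
  n1 <- nrow(tx); n2 <- ncol(tx)
  N <- n1 * n2
  c11 <- 1 / (1 - nu^2); c12 <- nu * c11; c33 <- 1 / (2 * (1 + nu))
  idx <- function(i, j) (j - 1L) * n1 + i          # u DOF; v DOF = N + idx
  cap <- 40L * N
  rows <- integer(cap); cols <- integer(cap); vals <- numeric(cap)
  np <- 0L
  rhs <- numeric(2L * N + 3L)
  eqn <- 0L
  add <- function(r, cc, v) {
    k <- length(cc)
    if (np + k > length(rows)) {
      rows <<- c(rows, integer(length(rows)))
      cols <<- c(cols, integer(length(cols)))
      vals <<- c(vals, numeric(length(vals)))
    }
    sel <- (np + 1L):(np + k)
    rows[sel] <<- r; cols[sel] <<- cc; vals[sel] <<- v
    np <<- np + k
  }
  d1 <- function(i, n) {
    if (i == 1) list(o = 0:2, w = c(-1.5, 2, -0.5) / d)
    else if (i == n) list(o = -(2:0), w = c(0.5, -2, 1.5) / d)
    else list(o = c(-1, 1), w = c(-0.5, 0.5) / d)
  }
  d2 <- function(i, n) {
    if (i == 1) list(o = 0:3, w = c(2, -5, 4, -1) / d^2)
    else if (i == n) list(o = -(3:0), w = c(-1, 4, -5, 2) / d^2)
    else list(o = -1:1, w = c(1, -2, 1) / d^2)
  }
  bc_x <- function(i, j, sx1, sy1) {
    # sigma_xx = 0 and sigma_xy = 0 on an x-normal edge
    eqn <<- eqn + 1L
    for (m in seq_along(sx1$o)) add(eqn, idx(i + sx1$o[m], j), c11 * sx1$w[m])
    for (m in seq_along(sy1$o)) add(eqn, N + idx(i, j + sy1$o[m]), c12 * sy1$w[m])
    eqn <<- eqn + 1L
    for (m in seq_along(sy1$o)) add(eqn, idx(i, j + sy1$o[m]), c33 * sy1$w[m])
    for (m in seq_along(sx1$o)) add(eqn, N + idx(i + sx1$o[m], j), c33 * sx1$w[m])
  }
  bc_y <- function(i, j, sx1, sy1) {
    # sigma_yy = 0 and sigma_xy = 0 on a y-normal edge
    eqn <<- eqn + 1L
    for (m in seq_along(sx1$o)) add(eqn, idx(i + sx1$o[m], j), c12 * sx1$w[m])
    for (m in seq_along(sy1$o)) add(eqn, N + idx(i, j + sy1$o[m]), c11 * sy1$w[m])
    eqn <<- eqn + 1L
    for (m in seq_along(sy1$o)) add(eqn, idx(i, j + sy1$o[m]), c33 * sy1$w[m])
    for (m in seq_along(sx1$o)) add(eqn, N + idx(i + sx1$o[m], j), c33 * sx1$w[m])
  }
  bc_corner <- function(i, j, sx1, sy1) {
    # free-free corner: both normal stresses vanish
    eqn <<- eqn + 1L
    for (m in seq_along(sx1$o)) add(eqn, idx(i + sx1$o[m], j), c11 * sx1$w[m])
    for (m in seq_along(sy1$o)) add(eqn, N + idx(i, j + sy1$o[m]), c12 * sy1$w[m])
    eqn <<- eqn + 1L
    for (m in seq_along(sx1$o)) add(eqn, idx(i + sx1$o[m], j), c12 * sx1$w[m])
    for (m in seq_along(sy1$o)) add(eqn, N + idx(i, j + sy1$o[m]), c11 * sy1$w[m])
  }
  for (j in seq_len(n2)) for (i in seq_len(n1)) {
    on_x <- (i == 1 || i == n1); on_y <- (j == 1 || j == n2)
    e_x <- if (i == 1) 1L else if (i == n1) 2L else NA_integer_
    e_y <- if (j == 1) 3L else if (j == n2) 4L else NA_integer_
    clamped <- (!is.na(e_x) && edges[e_x] == "clamped") ||
               (!is.na(e_y) && edges[e_y] == "clamped")
    if (clamped) {
      eqn <- eqn + 1L; add(eqn, idx(i, j), 1)
      eqn <- eqn + 1L; add(eqn, N + idx(i, j), 1)
      next
    }
    sx1 <- d1(i, n1); sy1 <- d1(j, n2)
    if (on_x && on_y) { bc_corner(i, j, sx1, sy1); next }
    if (on_x) { bc_x(i, j, sx1, sy1); next }
    if (on_y) { bc_y(i, j, sx1, sy1); next }
    sx2 <- d2(i, n1); sy2 <- d2(j, n2)
    # balance x: c11 u_xx + c33 u_yy + (c12 + c33) v_xy = t_x
    eqn <- eqn + 1L
    for (m in seq_along(sx2$o)) add(eqn, idx(i + sx2$o[m], j), c11 * sx2$w[m])
    for (m in seq_along(sy2$o)) add(eqn, idx(i, j + sy2$o[m]), c33 * sy2$w[m])
    for (mx in seq_along(sx1$o)) for (my in seq_along(sy1$o))
      add(eqn, N + idx(i + sx1$o[mx], j + sy1$o[my]),
          (c12 + c33) * sx1$w[mx] * sy1$w[my])
    rhs[eqn] <- tx[i, j]
    # balance y: c33 v_xx + c11 v_yy + (c12 + c33) u_xy = t_y
    eqn <- eqn + 1L
    for (m in seq_along(sx2$o)) add(eqn, N + idx(i + sx2$o[m], j), c33 * sx2$w[m])
    for (m in seq_along(sy2$o)) add(eqn, N + idx(i, j + sy2$o[m]), c11 * sy2$w[m])
    for (mx in seq_along(sx1$o)) for (my in seq_along(sy1$o))
      add(eqn, idx(i + sx1$o[mx], j + sy1$o[my]),
          (c12 + c33) * sx1$w[mx] * sy1$w[my])
    rhs[eqn] <- ty[i, j]
  }
  if (all(edges == "free")) {
    xs <- rep((seq_len(n1) - 1) * d, times = n2)
    ys <- rep((seq_len(n2) - 1) * d, each = n1)
    eqn <- eqn + 1L; add(rep(eqn, N), seq_len(N), rep(1 / N, N))
    eqn <- eqn + 1L; add(rep(eqn, N), N + seq_len(N), rep(1 / N, N))
    eqn <- eqn + 1L
    add(rep(eqn, 2L * N), c(seq_len(N), N + seq_len(N)),
        c(-ys, xs) / (N * d))
  }
  A <- Matrix::sparseMatrix(i = rows[seq_len(np)], j = cols[seq_len(np)],
                            x = vals[seq_len(np)], dims = c(eqn, 2L * N))
  sol <- if (eqn == 2L * N) {
    as.numeric(Matrix::solve(A, rhs[seq_len(eqn)]))
  } else {
    solve_sparse_lsq(A, rhs[seq_len(eqn)])
  }
  u <- matrix(sol[seq_len(N)], n1, n2)
  v <- matrix(sol[N + seq_len(N)], n1, n2)
  # residual of the solver's own interior balance stencils
  ii <- 2:(n1 - 1); jj <- 2:(n2 - 1)
  uxx <- (u[ii + 1, jj] - 2 * u[ii, jj] + u[ii - 1, jj]) / d^2
  uyy <- (u[ii, jj + 1] - 2 * u[ii, jj] + u[ii, jj - 1]) / d^2
  vxx <- (v[ii + 1, jj] - 2 * v[ii, jj] + v[ii - 1, jj]) / d^2
  vyy <- (v[ii, jj + 1] - 2 * v[ii, jj] + v[ii, jj - 1]) / d^2
  vxy <- (v[ii + 1, jj + 1] - v[ii - 1, jj + 1] - v[ii + 1, jj - 1] +
            v[ii - 1, jj - 1]) / (4 * d^2)
  uxy <- (u[ii + 1, jj + 1] - u[ii - 1, jj + 1] - u[ii + 1, jj - 1] +
            u[ii - 1, jj - 1]) / (4 * d^2)
  rx <- c11 * uxx + c33 * uyy + (c12 + c33) * vxy - tx[ii, jj]
  ry <- c33 * vxx + c11 * vyy + (c12 + c33) * uxy - ty[ii, jj]
  tn <- sqrt(sum(tx[ii, jj]^2 + ty[ii, jj]^2))
  resid <- if (tn > 0) sqrt(sum(rx^2 + ry^2)) / tn else sqrt(sum(rx^2 + ry^2))
  # stress from displacement gradients (2nd-order, one-sided at edges)
  ux <- apply_d1(u, d, 1); uy <- apply_d1(u, d, 2)
  vx <- apply_d1(v, d, 1); vy <- apply_d1(v, d, 2)
  list(sxx = c11 * ux + c12 * vy,
       syy = c12 * ux + c11 * vy,
       sxy = c33 * (uy + vx),
       residual = resid)
}

solve_sparse_lsq <- function(A, b) {
  # sparse QR is well conditioned; fall back to normal equations if the
  # decomposition is rank-revealing-unhappy on a degenerate input
  sol <- tryCatch(Matrix::qr.coef(Matrix::qr(A), b),
                  error = function(e) NULL)
  if (is.null(sol) || anyNA(sol)) {
    AtA <- Matrix::crossprod(A)
    sol <- Matrix::solve(AtA, Matrix::crossprod(A, b))
  }
  as.numeric(sol)
}

## second-order first derivative along axis (1 = rows/x, 2 = cols/y)
apply_d1 <- function(m, d, axis) {
  if (axis == 2) return(t(apply_d1(t(m), d, 1)))
  n <- nrow(m)
  out <- m
  out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * d)
  out[1, ] <- (-1.5 * m[1, ] + 2 * m[2, ] - 0.5 * m[3, ]) / d
  out[n, ] <- (1.5 * m[n, ] - 2 * m[n - 1, ] + 0.5 * m[n - 2, ]) / d
  out
}

## relative residual of the spectral discrete balance (periodic grids)
msm_balance_residual <- function(sxx, syy, sxy, tx, ty, d) {
  n1 <- nrow(sxx); n2 <- ncol(sxx)
  K1 <- matrix(fft_wavenumbers(n1, d), n1, n2)
  K2 <- matrix(fft_wavenumbers(n2, d), n1, n2, byrow = TRUE)
  ddx <- function(z) ifft2_real(fft2(z) * (1i * K1))
  ddy <- function(z) ifft2_real(fft2(z) * (1i * K2))
  rx <- ddx(sxx) + ddy(sxy) - tx
  ry <- ddx(sxy) + ddy(syy) - ty
  tn <- sqrt(sum(tx^2 + ty^2))
  rn <- sqrt(sum(rx^2 + ry^2))
  if (tn == 0) rn else rn / tn
}

#' Average-normal-stress profile along one axis
#'
#' Averages the average normal stress across the orthogonal axis and reports
#' peak positions and inter-peak distances as diagnostics of the stress
#' pattern wavelength.
#'
#' @param stress a [stress_field].
#' @param axis `"x"` or `"y"`: the axis along which the profile runs.
#' @return list with `r` (um), `profile` (N/m), `peaks` (um positions of
#'   local maxima) and `inter_peak` (successive peak distances, um).
#' @export
stress_profile <- function(stress, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(inherits(stress, "stress_field"))
  if (axis == "x") {
    r <- stress$x; p <- rowMeans(stress$avg_normal)
  } else {
    r <- stress$y; p <- colMeans(stress$avg_normal)
  }
  n <- length(p)
  is_peak <- if (n >= 3) {
    c(FALSE, p[2:(n - 1)] > p[1:(n - 2)] & p[2:(n - 1)] > p[3:n], FALSE)
  } else rep(FALSE, n)
  peaks <- r[is_peak]
  list(r = r, profile = p, peaks = peaks,
       inter_peak = if (length(peaks) > 1) diff(peaks) else numeric(0))
}
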