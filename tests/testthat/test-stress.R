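test_that("periodic MSM recovers compatible stress fields exactly", {
  sc <- gen_equilibrium_scene(stress_scene_spec(64, 4, n_modes = 4, seed = 3,
                                                amplitude = 2e-3,
                                                sheet_poisson = 0.5))
  st <- msm_solve(sc$traction, boundary = "periodic", sheet_poisson = 0.5,
                  flip_sign = FALSE)
  tru <- sc$stress$avg_normal - mean(sc$stress$avg_normal)
  expect_lt(rel_l2_mat(st$avg_normal, tru), 1e-10)
  expect_lt(attr(st, "balance_residual"), 1e-6)
  expect_equal(st$gauge, 0)
  # zero traction -> zero stress
  z <- traction_field(st$x, st$y, 0 * st$sxx, 0 * st$sxx)
  expect_true(all(msm_solve(z, boundary = "periodic")$sxx == 0))
})

test_that("the 1D strip force balance integrates to machine precision", {
  # uniform t_x from a free edge at x = 0, clamped far edge:
  # sigma_xx(x) = t0 * x; t0 = 100 Pa at x = 100 um -> 0.01 N/m
  n1 <- 51; n2 <- 7; d <- 2
  xs <- (0:(n1 - 1)) * d; ys <- (0:(n2 - 1)) * d
  tf <- traction_field(xs, ys, matrix(100, n1, n2), matrix(0, n1, n2))
  st <- msm_solve(tf, boundary = c("free", "clamped", "free", "free"),
                  sheet_poisson = 0, flip_sign = FALSE)
  expected <- matrix(100e-6 * xs, n1, n2)
  expect_lt(max(abs(st$sxx - expected)), 1e-10 * max(expected))
  expect_equal(st$sxx[xs == 100, 4], 0.01, tolerance = 1e-9)
  expect_lt(max(abs(st$syy)), 1e-12)
  expect_lt(max(abs(st$sxy)), 1e-12)
})

test_that("free-boundary MSM balances net-balanced tractions", {
  n <- 33; d <- 4
  xs <- (0:(n - 1)) * d
  # localized dipole pair along x, zero net force
  tx <- matrix(0, n, n)
  g <- function(x0, y0) outer(xs, xs, function(x, y)
    exp(-((x - x0)^2 + (y - y0)^2) / (2 * 15^2)))
  tx <- 80 * g(40, 64) - 80 * g(88, 64)
  tx <- tx - mean(tx)
  tf <- traction_field(xs, xs, tx, matrix(0, n, n))
  st <- msm_solve(tf, boundary = "free", sheet_poisson = 0.4,
                  flip_sign = FALSE)
  expect_lt(attr(st, "balance_residual"), 1e-6)
  # unbalanced traction is rejected with advice
  tbad <- traction_field(xs, xs, matrix(50, n, n), matrix(0, n, n))
  expect_error(msm_solve(tbad, boundary = "free", flip_sign = FALSE),
               "remove the mean")
})

test_that("sigma-bar and principal difference respect axis-exchange symmetry", {
  sc <- gen_equilibrium_scene(stress_scene_spec(48, 4, n_modes = 3, seed = 9,
                                                amplitude = 2e-3))
  st <- msm_solve(sc$traction, boundary = "periodic", flip_sign = FALSE)
  # exchanging the grid axes (x <-> y) maps tx <-> ty and transposes every
  # field; the rotation-invariant scalars must transpose along
  tr_t <- traction_field(st$y, st$x, t(sc$traction$v), t(sc$traction$u))
  st_t <- msm_solve(tr_t, boundary = "periodic", flip_sign = FALSE)
  expect_equal(st_t$avg_normal, t(st$avg_normal), tolerance = 1e-9)
  expect_equal(st_t$smax - st_t$smin, t(st$smax - st$smin), tolerance = 1e-9)
})

test_that("MSM sheet-Poisson sensitivity follows the analytic mode structure", {
  # shear scenes are exactly independent of the assumed sheet Poisson ratio
  k <- 2 * pi * 3 / (48 * 4)
  shear <- stress_scene_spec(48, 4, stress_modes = list(
    list(amplitude = 2e-3, wavevector = c(k, 0), pattern = "shear")))
  sc <- gen_equilibrium_scene(shear)
  a <- msm_solve(sc$traction, boundary = "periodic", sheet_poisson = 0.5,
                 flip_sign = FALSE)
  b <- msm_solve(sc$traction, boundary = "periodic", sheet_poisson = 0.2,
                 flip_sign = FALSE)
  expect_lt(max(abs(a$smax - b$smax)), 1e-12)
  # longitudinal scenes scale sigma-bar by (1 + nu') / (1 + nu_gen)
  comp <- stress_scene_spec(48, 4, stress_modes = list(
    list(amplitude = 2e-3, wavevector = c(k, 0), pattern = "compression")),
    sheet_poisson = 0.5)
  scc <- gen_equilibrium_scene(comp)
  a <- msm_solve(scc$traction, boundary = "periodic", sheet_poisson = 0.5,
                 flip_sign = FALSE)
  b <- msm_solve(scc$traction, boundary = "periodic", sheet_poisson = 0.2,
                 flip_sign = FALSE)
  ratio <- sd(as.vector(b$avg_normal)) / sd(as.vector(a$avg_normal))
  expect_equal(ratio, 1.2 / 1.5, tolerance = 1e-6)
})

test_that("principal decomposition matches the eigen oracle", {
  xs <- (0:3) * 4
  iso <- stress_field(xs, xs, matrix(2e-3, 4, 4), matrix(2e-3, 4, 4),
                      matrix(0, 4, 4))
  expect_true(all(is.na(iso$theta)))
  expect_equal(iso$smax, iso$smin)
  sh <- stress_field(xs, xs, matrix(0, 4, 4), matrix(0, 4, 4),
                     matrix(1e-3, 4, 4))
  expect_equal(sh$smax[1, 1], 1e-3)
  expect_equal(sh$smin[1, 1], -1e-3)
  expect_equal(sh$theta[1, 1], pi / 4)
  # random symmetric tensors against base eigen()
  set.seed(11)
  for (i in 1:20) {
    m <- matrix(rnorm(3), 1)
    p <- sheetmech:::principal_decomposition_raw(m[1], m[2], m[3])
    ev <- eigen(matrix(c(m[1], m[3], m[3], m[2]), 2, 2), symmetric = TRUE)
    expect_equal(c(p$smax, p$smin), ev$values, tolerance = 1e-12)
    expect_equal((p$smax + p$smin) / 2, (m[1] + m[2]) / 2, tolerance = 1e-12)
  }
})

test_that("stress profiles average correctly and locate peaks", {
  n <- 64; d <- 4
  xs <- (0:(n - 1)) * d
  # uniform field: flat profile, no peaks
  u <- stress_field(xs, xs, matrix(1e-3, n, n), matrix(1e-3, n, n),
                    matrix(0, n, n))
  pu <- stress_profile(u, "x")
  expect_equal(diff(range(pu$profile)), 0)
  expect_length(pu$peaks, 0)
  # single mode: inter-peak distance = wavelength
  k <- 2 * pi * 4 / (n * d)
  s <- stress_field(xs, xs, outer(1e-3 * sin(k * xs), rep(1, n)),
                    matrix(0, n, n), matrix(0, n, n))
  ps <- stress_profile(s, "x")
  expect_equal(mean(ps$inter_peak), 2 * pi / k, tolerance = 0.1)
  # equals the direct row-average oracle exactly
  sc <- gen_equilibrium_scene(stress_scene_spec(32, 4, n_modes = 2, seed = 4))
  p <- stress_profile(sc$stress, "x")
  expect_equal(p$profile, rowMeans(sc$stress$avg_normal))
})
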