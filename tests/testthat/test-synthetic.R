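test_that("hex pattern is a jittered triangular lattice with exact spacing", {
  p <- gen_hex_pattern(spacing = 50, jitter_sd = 0, n_points = 625)
  expect_equal(nrow(p$coordinates), 625)
  # interior points: mean distance to the 6 nearest neighbours is the
  # lattice constant, with zero spread
  s <- knn_spacing(p, k = 6, edge_margin = 75)
  expect_equal(s$mean_spacing, 50, tolerance = 1e-12)
  expect_equal(s$sd_spacing, 0, tolerance = 1e-9)
  # minimum pairwise distance equals the lattice constant
  p35 <- gen_hex_pattern(spacing = 35, jitter_sd = 0, n_points = 100)
  expect_equal(min(dist(p35$coordinates)), 35, tolerance = 1e-9)
})

test_that("jittered hex pattern keeps mean 6-NN distance near nominal", {
  p <- gen_hex_pattern(spacing = 50, jitter_sd = 5, n_points = 676, seed = 1)
  oracle <- brute_force_knn(p$coordinates, 6)
  # interior points only (margin 1.5 spacings)
  b <- p$domain_bounds
  xy <- p$coordinates
  keep <- xy[, 1] >= b[1] + 75 & xy[, 1] <= b[2] - 75 &
          xy[, 2] >= b[3] + 75 & xy[, 2] <= b[4] - 75
  expect_gt(sum(keep), 300)
  expect_lt(abs(mean(oracle[keep]) - 50) / 50, 0.03)
})

test_that("generators are deterministic under seed and validate input", {
  a <- gen_hex_pattern(50, 5, 100, seed = 3)
  b <- gen_hex_pattern(50, 5, 100, seed = 3)
  expect_identical(a$coordinates, b$coordinates)
  expect_error(gen_hex_pattern(-1, 0, 100), class = "sheetmech_invalid_parameter")
  expect_error(field_spec(64, node_spacing = 0), class = "sheetmech_invalid_parameter")
  expect_error(fa_scene_spec(10, frame_interval = 0),
               class = "sheetmech_invalid_parameter")
  f1 <- gen_velocity_field(field_spec(32, 10, fluctuation_sd = 2,
                                      kernel_scale = 20, seed = 9))
  f2 <- gen_velocity_field(field_spec(32, 10, fluctuation_sd = 2,
                                      kernel_scale = 20, seed = 9))
  expect_identical(f1$u, f2$u)
})

test_that("velocity field drift and fluctuation structure behave as specified", {
  # pure drift: every vector identical with the requested magnitude
  f <- gen_velocity_field(field_spec(16, 10, drift_speed = 20,
                                     drift_direction = c(1, 0)))
  expect_true(all(abs(f$u - 20) < 1e-12))
  expect_true(all(abs(f$v) < 1e-12))
  # unsmoothed fluctuations are spatially white: lag-1 sample correlation ~ 0
  fw <- gen_velocity_field(field_spec(64, 10, fluctuation_sd = 1,
                                      kernel_scale = 0, seed = 4))
  v <- fw$v - mean(fw$v)
  lag1 <- cor(as.vector(v[-1, ]), as.vector(v[-64, ]))
  expect_lt(abs(lag1), 3 / sqrt(63 * 64))
  # oversized kernel warns that the correlation length is unresolvable
  expect_warning(gen_velocity_field(field_spec(16, 10, fluctuation_sd = 1,
                                               kernel_scale = 100)),
                 "not be resolvable")
})

test_that("equilibrium scenes satisfy the discrete force balance", {
  # single direct mode: analytic divergence
  k <- 2 * pi * 3 / (64 * 4)
  sp <- stress_scene_spec(64, 4, stress_modes = list(
    list(amplitude = 1e-3, wavevector = c(k, 0), pattern = "xx", phase = 0)))
  sc <- gen_equilibrium_scene(sp)
  xs <- sc$stress$x
  expect_equal(sc$stress$sxx[, 1], 1e-3 * sin(k * xs), tolerance = 1e-12)
  expect_equal(sc$traction$u[, 1], 1e-3 * k * cos(k * xs) * 1e6,
               tolerance = 1e-9)
  expect_true(all(sc$traction$v == 0))
  # zero modes: valid degenerate scene
  sc0 <- gen_equilibrium_scene(stress_scene_spec(32, 4, stress_modes = list()))
  expect_true(all(sc0$traction$u == 0) && all(sc0$stress$sxx == 0))
  # random scenes: residual at machine precision, several seeds
  for (s in 1:3) {
    sc <- gen_equilibrium_scene(stress_scene_spec(64, 4, n_modes = 4, seed = s))
    expect_lt(balance_residual(sc$stress, sc$traction), 1e-10)
    expect_identical(sc$stress$sxy, t(t(sc$stress$sxy)))  # symmetric storage
  }
  # enveloped (localized) scene balances too
  sce <- gen_equilibrium_scene(stress_scene_spec(64, 4, n_modes = 3,
                                                 envelope = "hann", seed = 2))
  expect_lt(balance_residual(sce$stress, sce$traction), 1e-10)
})

test_that("bead pairs are consistent with the displacement applied", {
  spec <- bead_image_spec(c(128, 128), px_size = 0.5, bead_density = 0.05,
                          noise_sd = 0, seed = 2)
  # zero displacement: identical images, intensity conserved
  pr <- gen_bead_pair(spec, NULL)
  expect_identical(pr$reference, pr$stressed)
  # uniform integer displacement: stressed equals translated reference in
  # the interior, and total intensity is conserved for interior beads
  xs <- c(0, 63.5)
  u <- vector_field(xs, xs, matrix(3, 2, 2), matrix(0, 2, 2), units = "px")
  pr2 <- gen_bead_pair(spec, u)
  expect_equal(pr2$stressed[10:120, 5:120], pr2$reference[7:117, 5:120],
               tolerance = 1e-10)
  expect_equal(nrow(pr2$beads_px), round(0.05 * (128 * 0.5)^2))
  expect_error(bead_image_spec(c(64, 64), px_size = 0.5, psf_sigma = 0),
               class = "sheetmech_invalid_parameter")
})

test_that("fa movie ground truth matches its sampling model", {
  # appearance_rate = 0: all tracks start on the first frame
  sp0 <- fa_scene_spec(20, n_frames = 20, appearance_rate = 0, seed = 2)
  tr0 <- gen_fa_movie(sp0, render = FALSE)$truth
  expect_true(all(tr0$birth_frame == 1L))
  # lifetimes: frames times the frame interval
  expect_equal(tr0$lifetime_min,
               (tr0$death_frame - tr0$birth_frame + 1L) * sp0$frame_interval)
  # exponential lifetimes with mean 14 min at 2-min frames: sample mean of
  # uncensored tracks within 2 SEM
  sp <- fa_scene_spec(200, lifetime_mean = 14, frame_interval = 2,
                      n_frames = 100, appearance_rate = 4, seed = 7)
  tr <- gen_fa_movie(sp, render = FALSE)$truth
  life <- tr$lifetime_min[!tr$censored]
  sem <- sd(life) / sqrt(length(life))
  expect_lt(abs(mean(life) - 14), 2 * sem)
  # rendered movie consistent with table: frame of a known track shows signal
  spr <- fa_scene_spec(3, n_frames = 6, appearance_rate = 0, noise_sd = 0,
                       image_shape = c(80, 80), seed = 5)
  mv <- gen_fa_movie(spr)
  i <- round(mv$truth$x_um[1] / spr$px_size) + 1
  j <- round(mv$truth$y_um[1] / spr$px_size) + 1
  t_in <- mv$truth$birth_frame[1]
  expect_gt(mv$frames[[t_in]][i, j], spr$peak_intensity / 2)
})
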