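test_that("velocity decomposition projects and centres the lateral component", {
  xs <- (0:7) * 10
  # uniform flow along the migration axis: no lateral fluctuation
  f <- vector_field(xs, xs, matrix(15, 8, 8), matrix(0, 8, 8), units = "um/hr")
  d <- decompose_velocity(f, c(1, 0))
  expect_true(all(d$fluctuation == 0))
  expect_equal(mean(d$axial), 15)
  # +1/-1 lateral in equal numbers: zero mean, fluctuations equal values
  V <- matrix(rep(c(1, -1), 32), 8, 8)
  f2 <- vector_field(xs, xs, matrix(0, 8, 8), V, units = "um/hr")
  d2 <- decompose_velocity(f2, c(1, 0))
  expect_equal(d2$lateral_mean, 0)
  expect_equal(d2$fluctuation, V)
  # random field: fluctuation mean zero by construction; energy preserved
  set.seed(1)
  f3 <- vector_field(xs, xs, matrix(rnorm(64), 8, 8), matrix(rnorm(64), 8, 8),
                     units = "um/hr")
  d3 <- decompose_velocity(f3, c(2, 1))
  expect_lt(abs(mean(d3$fluctuation)), 1e-12)
  expect_equal(d3$axial^2 + d3$lateral^2, f3$u^2 + f3$v^2, tolerance = 1e-12)
  expect_error(decompose_velocity(f3, c(0, 0)),
               class = "sheetmech_invalid_parameter")
})

test_that("binned correlation equals the brute-force double loop exactly", {
  set.seed(7)
  z <- sheetmech:::gauss_smooth_periodic(matrix(rnorm(32 * 32), 32, 32), 2)
  z <- z - mean(z)
  fast <- velocity_correlation(z, spacing = 10)
  oracle <- brute_force_correlation(z, 10)
  expect_equal(fast$r, oracle$r)
  expect_equal(fast$n_pairs, oracle$n_pairs)
  expect_equal(fast$C, oracle$C, tolerance = 1e-10)
  # with invalid nodes masked out
  z2 <- z; z2[c(3, 40, 100, 500)] <- NA
  fast2 <- velocity_correlation(z2, spacing = 10)
  oracle2 <- brute_force_correlation(z2, 10)
  expect_equal(fast2$C, oracle2$C, tolerance = 1e-10)
  expect_equal(fast2$n_pairs, oracle2$n_pairs)
})

test_that("correlation curves are normalized, symmetric and white-field-flat", {
  set.seed(8)
  z <- matrix(rnorm(48 * 48), 48, 48); z <- z - mean(z)
  cv <- velocity_correlation(z, spacing = 10)
  expect_equal(cv$C[1], 1)                       # C(0) = 1
  expect_true(all(abs(cv$C[-1]) < 3 / sqrt(cv$n_pairs[-1])))
  # global sign flip leaves the curve unchanged
  cv2 <- velocity_correlation(-z, spacing = 10)
  expect_equal(cv$C, cv2$C)
  # zero-variance field is rejected
  expect_error(velocity_correlation(matrix(0, 8, 8), spacing = 10),
               class = "sheetmech_data_error")
})

test_that("threshold crossing is interpolated and censored correctly", {
  r <- seq(0, 500, by = 10)
  L <- 60
  cv <- correlation_curve(r, exp(-r / L), rep(100, length(r)))
  expect_equal(correlation_length(cv), L * log(100), tolerance = 5)
  # curve never reaching the threshold: censored NA
  cv2 <- correlation_curve(r, 0.5 + 0 * r, rep(100, length(r)))
  len <- correlation_length(cv2)
  expect_true(is.na(len))
  expect_equal(attr(len, "censored_at"), 500)
})

test_that("correlation length recovers the generator kernel scale", {
  # field of view ~ 55 kernel scales; curve averaged over seeds, plateau
  # deficit removed, antitonic fit before the 0.01 crossing
  est <- function(l, spacing, seeds, n_nodes = 128) {
    curves <- lapply(seeds, function(s) {
      fs <- field_spec(n_nodes, spacing, drift_speed = 20, fluctuation_sd = 3,
                       kernel_scale = l, seed = s)
      velocity_correlation(decompose_velocity(gen_velocity_field(fs), c(1, 0)))
    })
    cv <- plateau_correct(average_correlation(curves))
    keep <- cv$r <= 0.5 * max(cv$r)
    C <- -stats::isoreg(cv$r[keep], -cv$C[keep])$yf
    sheetmech:::crossing_length(cv$r[keep], C, 0.01)
  }
  # scaled-down study (128^2 nodes, 5 seeds); the acceptance study runs the
  # full 256^2 x 10-seed version
  ests <- sapply(c(12, 23, 47), function(l)
    est(l, l * 55 / 128, 1:5))
  expect_lt(max(abs(ests / (4.2919 * c(12, 23, 47)) - 1)), 0.15)
  expect_true(all(diff(ests) > 0))  # monotone in the kernel scale
})

test_that("stress correlation matches its oracle and handles both modes", {
  n <- 32; d <- 8
  xs <- (0:(n - 1)) * d
  k <- 2 * pi * 4 / (n * d)
  sig <- outer(sin(k * xs), rep(1, n))
  st <- stress_field(xs, xs, sig * 1e-3, sig * 1e-3, matrix(0, n, n))
  sc <- stress_correlation(st, mode = "scalar")
  oracle <- brute_force_correlation(st$avg_normal - mean(st$avg_normal), d)
  expect_equal(sc$C, oracle$C, tolerance = 1e-10)
  expect_equal(sheetmech:::crossing_length(sc$r, sc$C, 0.01),
               sheetmech:::crossing_length(oracle$r, oracle$C, 0.01))
  # uniform stress: zero variance error
  u <- stress_field(xs, xs, matrix(1e-3, n, n), matrix(1e-3, n, n),
                    matrix(0, n, n))
  expect_error(stress_correlation(u, "scalar"), class = "sheetmech_data_error")
  # nematic mode: normalized at the origin
  set.seed(3)
  r1 <- sheetmech:::gauss_smooth_periodic(matrix(rnorm(n * n), n, n), 2)
  r2 <- sheetmech:::gauss_smooth_periodic(matrix(rnorm(n * n), n, n), 2)
  st2 <- stress_field(xs, xs, (2 * r1 + 0.5 * r2) * 1e-3, r1 * 1e-3,
                      r2 * 1e-3)
  nc <- stress_correlation(st2, mode = "nematic")
  expect_equal(nc$C[1], 1, tolerance = 1e-9)
})

test_that("stress correlation length tracks the field correlation scale", {
  n <- 128; d <- 4
  xs <- (0:(n - 1)) * d
  est <- function(sig_nodes, seeds) {
    curves <- lapply(seeds, function(s) {
      set.seed(s)
      z <- sheetmech:::gauss_smooth_periodic(matrix(rnorm(n * n), n, n),
                                             sig_nodes)
      st <- stress_field(xs, xs, z * 1e-3, 0.8 * z * 1e-3, matrix(0, n, n))
      stress_correlation(st, "scalar")
    })
    cv <- plateau_correct(average_correlation(curves))
    keep <- cv$r <= 0.5 * max(cv$r)
    iso <- -stats::isoreg(cv$r[keep], -cv$C[keep])$yf
    sheetmech:::crossing_length(cv$r[keep], iso, 0.01)
  }
  # quantitative recovery where the view spans >= 55 correlation scales
  got2 <- est(2, 1:6)
  expect_lt(abs(got2 / (4.2919 * 2 * d) - 1), 0.1)
  # and monotone growth with the field scale
  expect_gt(est(4, 1:6), got2)
})

test_that("sheet speed estimators agree with the programmed front motion", {
  # masks advancing 20 um per hour-frame
  masks <- lapply(0:3, function(t) {
    m <- matrix(FALSE, 100, 50)
    m[1:(40 + 20 * t), ] <- TRUE
    m
  })
  sp <- sheet_speed(NULL, method = "front-edge", dt = 60, px_size = 1,
                    masks = masks)
  expect_equal(sp$speed_um_hr, 20)
  # static mask: zero speed
  sp0 <- sheet_speed(NULL, method = "front-edge", dt = 60, px_size = 1,
                     masks = masks[c(1, 1, 1)])
  expect_equal(sp0$speed_um_hr, 0)
  expect_error(sheet_speed(NULL, method = "front-edge", dt = 10,
                           masks = list(matrix(FALSE, 5, 5))),
               class = "sheetmech_data_error")
  # front-edge and piv-mean agree on a synthetic advancing monolayer
  fs <- field_spec(32, 8, drift_speed = 25, fluctuation_sd = 3,
                   kernel_scale = 30, seed = 12)
  mv <- gen_texture_movie(fs, n_frames = 5, dt_min = 30, px_size = 1,
                          image_shape = c(256, 256), front_x0_um = 150,
                          front_speed_um_hr = 25, noise_sd = 0.01, seed = 12)
  fe <- sheet_speed(NULL, method = "front-edge", dt = 30, px_size = 1,
                    masks = mv$masks)
  pm <- sheet_speed(mv$frames, method = "piv-mean", dt = 30, px_size = 1,
                    window_px = 32, masks = mv$masks)
  expect_lt(abs(fe$speed_um_hr - 25) / 25, 0.1)
  expect_lt(abs(pm$speed_um_hr - 25) / 25, 0.1)
})

test_that("delta speed reports the mean change across the switch", {
  prof <- structure(list(time_hr = 0:6, front_um = cumsum(c(0, rep(10, 3), rep(15, 3))),
                         speed_um_hr = NA,
                         speed_series = c(10, 10, 10, 15, 15, 15),
                         method = "front-edge"),
                    class = "front_profile")
  dv <- delta_speed(prof, 3)
  expect_equal(as.numeric(dv), 5)
  expect_equal(attr(dv, "pre"), 10)
  # constant speed: zero change
  prof$speed_series <- rep(12, 6)
  expect_equal(as.numeric(delta_speed(prof, 3)), 0)
  expect_error(delta_speed(prof, 7), class = "sheetmech_invalid_parameter")
  expect_error(delta_speed(prof, 0.5), class = "sheetmech_invalid_parameter")
})
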