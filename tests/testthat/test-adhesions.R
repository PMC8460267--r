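test_that("segmentation finds rendered patches with faithful geometry", {
  # blank frame: nothing
  set.seed(1)
  blank <- matrix(rnorm(200 * 200, sd = 5), 200, 200)
  expect_equal(nrow(segment_adhesions(blank, px_size = 0.1)), 0)
  # two rendered elliptical patches: correct count, area within 10%
  img <- matrix(0, 200, 200)
  r1 <- sheetmech:::render_ellipse_patch(img, 60, 60, 15, 8, 0.4, 800)
  r2 <- sheetmech:::render_ellipse_patch(r1$img, 140, 130, 10, 6, 2.1, 800)
  frame <- r2$img + matrix(rnorm(200 * 200, sd = 10), 200, 200)
  det <- segment_adhesions(frame, px_size = 0.1, background_scale = 40)
  expect_equal(nrow(det), 2)
  truth_areas <- sort(c(r1$n_px, r2$n_px)) * 0.1^2
  expect_lt(max(abs(sort(det$area_um2) - truth_areas) / truth_areas), 0.1)
  # ellipse consistency: length^2 >= 4 area / pi
  expect_true(all(det$length_um^2 >= 4 * det$area_um2 / pi))
  # min_area sweep: detection count monotonically non-increasing
  counts <- sapply(c(0.1, 0.5, 1.0, 2.0), function(a)
    nrow(segment_adhesions(frame, px_size = 0.1, background_scale = 40,
                           min_area = a)))
  expect_true(all(diff(counts) <= 0))
})

test_that("areas scale exactly with the pixel calibration", {
  img <- matrix(0, 120, 120)
  r <- sheetmech:::render_ellipse_patch(img, 60, 60, 12, 7, 1.0, 800)
  frame <- r$img + matrix(rnorm(120 * 120, sd = 8), 120, 120)
  d1 <- segment_adhesions(frame, px_size = 0.1, background_scale = 40)
  d2 <- segment_adhesions(frame, px_size = 0.2, background_scale = 40)
  expect_equal(d2$area_um2, 4 * d1$area_um2)
  expect_equal(d2$length_um, 2 * d1$length_um)
})

test_that("tracking links stationary detections and respects the gate", {
  # one stationary detection over 10 frames at 2 min: lifetime 20 min
  det <- lapply(1:10, function(t)
    data.frame(x_um = 5, y_um = 5, area_um2 = 1, length_um = 1.5,
               mean_intensity = 100))
  tk <- track_adhesions(det, max_link_dist = 2, frame_interval = 2)
  expect_equal(nrow(tk$tracks), 1)
  expect_equal(tk$tracks$lifetime_min, 20)
  expect_true(tk$tracks$censored)  # touches both movie ends
  # detections jumping farther than the gate are not linked
  det2 <- list(
    data.frame(x_um = c(0, 30), y_um = c(0, 0), area_um2 = 1, length_um = 1,
               mean_intensity = 1),
    data.frame(x_um = c(10, 40), y_um = c(0, 0), area_um2 = 1, length_um = 1,
               mean_intensity = 1))
  tk2 <- track_adhesions(det2, max_link_dist = 2, frame_interval = 2)
  expect_equal(nrow(tk2$tracks), 4)   # all terminated, no swap links
  # every detection belongs to exactly one track
  expect_equal(sum(tk2$tracks$death_frame - tk2$tracks$birth_frame + 1), 4)
  expect_false(any(is.na(tk2$detections$track)))
})

test_that("the synthetic fa pipeline recovers tracks and lifetimes", {
  spec <- fa_scene_spec(n_adhesions = 60, lifetime_mean = 14,
                        frame_interval = 2, n_frames = 60,
                        appearance_rate = 2, image_shape = c(300, 300),
                        seed = 7)
  mv <- gen_fa_movie(spec)
  dets <- lapply(mv$frames, segment_adhesions, px_size = spec$px_size)
  tk <- track_adhesions(dets, frame_interval = 2)
  tr <- mv$truth
  tt <- tk$tracks
  hit <- 0; life_ok <- 0
  for (i in seq_len(nrow(tr))) {
    d2 <- (tt$x_um - tr$x_um[i])^2 + (tt$y_um - tr$y_um[i])^2
    j <- which.min(d2)
    if (d2[j] < 1.5^2) {
      hit <- hit + 1
      if (abs(tt$lifetime_min[j] - tr$lifetime_min[i]) <= 2)
        life_ok <- life_ok + 1
    }
  }
  expect_gte(hit / nrow(tr), 0.95)
  expect_gte(life_ok / nrow(tr), 0.95)
  # censoring-excluded mean within 2 SEM of the truth mean
  ls <- lifetime_summary(tk)
  truth_life <- tr$lifetime_min[!tr$censored]
  sem <- sd(truth_life) / sqrt(length(truth_life))
  expect_lt(abs(ls$mean_min - mean(truth_life)), 2 * sem)
})

test_that("excluding censored tracks keeps the lifetime mean unbiased", {
  # with an observation window long relative to the mean lifetime, the
  # censor-excluded sample mean stays within 2 SEM of the nominal mean,
  # and every censored track is truncated by the movie boundary
  spec <- fa_scene_spec(n_adhesions = 300, lifetime_mean = 10,
                        frame_interval = 2, n_frames = 80,
                        appearance_rate = 4, seed = 3)
  tr <- gen_fa_movie(spec, render = FALSE)$truth
  life <- tr$lifetime_min[!tr$censored]
  sem <- sd(life) / sqrt(length(life))
  expect_lt(abs(mean(life) - 10), 2 * sem)
  cens <- tr[tr$censored, ]
  expect_true(all(cens$birth_frame <= 1 | cens$death_frame >= 80))
})

test_that("contact area segments the cytoplasmic region and density follows", {
  # rendered disk of radius 20 um at 0.1 um/px
  n <- 600
  xs <- (1:n)
  d2 <- outer((xs - 300)^2, (xs - 300)^2, "+")
  frame <- 100 * (d2 <= 200^2) + matrix(rnorm(n * n, sd = 2), n, n)
  ca <- contact_area(frame, cytoplasm_threshold = 0.4, px_size = 0.1,
                     n_adhesions = 12)
  expect_lt(abs(ca$area_um2 - pi * 400) / (pi * 400), 0.05)
  expect_equal(ca$density_per_um2, 12 / ca$area_um2)
  # full-frame signal: area equals the field of view
  full <- matrix(100, 50, 50)
  expect_equal(contact_area(full, 0.2, px_size = 0.1)$area_um2,
               50 * 50 * 0.01)
  expect_error(contact_area(matrix(0, 5, 5), 0.9, px_size = 0.1),
               class = "sheetmech_data_error")
  # density with a simple count: 12 adhesions on 600 um^2 -> 0.02
  expect_equal(12 / 600, 0.02)
})

test_that("lifetime summaries handle small and censored inputs", {
  tab <- data.frame(lifetime_min = c(10, 20, 30), censored = FALSE)
  s <- lifetime_summary(tab)
  expect_equal(s$mean_min, 20)
  expect_equal(s$n, 3)
  one <- data.frame(lifetime_min = 12, censored = FALSE)
  expect_true(is.na(lifetime_summary(one)$sd_min))
  allc <- data.frame(lifetime_min = c(4, 6), censored = TRUE)
  expect_error(lifetime_summary(allc), class = "sheetmech_data_error")
  expect_equal(lifetime_summary(allc, exclude_censored = FALSE)$mean_min, 5)
})
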