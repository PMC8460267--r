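#' Specification of a synthetic focal-adhesion movie
#'
#' Adhesions appear at random positions and frames, persist for exponential
#' lifetimes discretized to frames (mean `lifetime_mean`), and are rendered as
#' sharp-edged elliptical patches lightly blurred by the PSF.  A ground-truth
#' table (birth/death frames, pixel-accurate area, major-axis length) is
#' returned alongside the rendered movie.
#'
#' @param n_adhesions total number of adhesions in the scene.
#' @param lifetime_mean mean lifetime, minutes.
#' @param area_mean mean adhesion area, um^2.
#' @param frame_interval frame interval, minutes.
#' @param n_frames number of frames.
#' @param appearance_rate new adhesions per frame after frame 1; `0` puts all
#'   births at the first frame.
#' @param image_shape frame size, px (length 1 or 2).
#' @param px_size pixel calibration, um/px.
#' @param peak_intensity patch peak counts; `noise_sd` additive noise counts.
#' @param min_separation minimum centre-to-centre distance between
#'   concurrently placed adhesions, um.
#' @param noise_sd additive Gaussian noise sd, counts.
#' @param seed integer seed.
#' @return object of class `fa_scene_spec`.
#' @export
fa_scene_spec <- function(n_adhesions, lifetime_mean = 14, area_mean = 1.5,
                          frame_interval = 2, n_frames = 60L,
                          appearance_rate = 0, image_shape = c(300L, 300L),
                          px_size = 0.1, peak_intensity = 800,
                          min_separation = 4, noise_sd = 15, seed = 1L) {
  if (frame_interval <= 0) stop_invalid("frame_interval must be > 0")
  if (lifetime_mean <= 0) stop_invalid("lifetime_mean must be > 0")
  if (length(image_shape) == 1) image_shape <- rep(image_shape, 2)
  structure(list(n_adhesions = as.integer(n_adhesions),
                 lifetime_mean = lifetime_mean, area_mean = area_mean,
                 frame_interval = frame_interval, n_frames = as.integer(n_frames),
                 appearance_rate = appearance_rate,
                 image_shape = as.integer(image_shape), px_size = px_size,
                 peak_intensity = peak_intensity,
                 min_separation = min_separation, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "fa_scene_spec")
}

## Render one elliptical patch: pixels with centre inside the ellipse get the
## peak intensity, then the patch is blurred (sigma 0.7 px).  Returns the
## pixel mask (for ground-truth area) and adds the patch into `img`.
render_ellipse_patch <- function(img, cx, cy, a_px, b_px, phi, peak) {
  r <- ceiling(max(a_px, b_px)) + 3L
  i0 <- max(1L, round(cx) - r); i1 <- min(nrow(img), round(cx) + r)
  j0 <- max(1L, round(cy) - r); j1 <- min(ncol(img), round(cy) + r)
  ii <- i0:i1; jj <- j0:j1
  dx <- matrix(ii - cx, length(ii), length(jj))
  dy <- matrix(jj - cy, length(ii), length(jj), byrow = TRUE)
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  inside <- (xr / a_px)^2 + (yr / b_px)^2 <= 1
  patch <- matrix(0, length(ii), length(jj))
  patch[inside] <- peak
  patch <- gauss_smooth_small(patch, 0.7)
  img[ii, jj] <- img[ii, jj] + patch
  list(img = img, n_px = sum(inside))
}

## small-kernel separable Gaussian blur with reflective edges (non-periodic)
gauss_smooth_small <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  g <- exp(-(-r:r)^2 / (2 * sigma^2)); g <- g / sum(g)
  pad <- function(m, k) rbind(m[rep(1, k), , drop = FALSE], m,
                              m[rep(nrow(m), k), , drop = FALSE])
  conv1 <- function(m) {
    p <- pad(m, r)
    out <- matrix(0, nrow(m), ncol(m))
    for (s in -r:r) out <- out + g[s + r + 1] * p[(1 + r + s):(nrow(m) + r + s), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(x))))
}

#' Generate a focal-adhesion movie with ground truth
#'
#' @param spec a [fa_scene_spec].
#' @param render render the frames (default); `FALSE` returns the ground-truth
#'   table only (`frames = NULL`), for statistical checks that do not need
#'   images.  The truth table is identical either way, except that the
#'   pixel-accurate `area_um2` requires rendering (`NA` otherwise).
#' @return list with `frames` (list of count matrices, or `NULL`), `truth`
#'   (data.frame: `track_id`, `birth_frame`, `death_frame`, `lifetime_min`,
#'   `x_um`, `y_um`, `area_um2`, `length_um`, `censored`), and the spec.
#' @export
gen_fa_movie <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "fa_scene_spec"))
  shp <- spec$image_shape
  n <- spec$n_adhesions
  with_seed(derive_seed(spec$seed, "fa_movie"), {
    mean_frames <- spec$lifetime_mean / spec$frame_interval
    # lifetimes: 1 + geometric, mean = mean_frames (exponential discretized)
    p <- 1 / max(mean_frames, 1)
    life <- 1L + stats::rgeom(n, p)
    if (spec$appearance_rate <= 0) {
      birth <- rep(1L, n)
    } else {
      gaps <- stats::rexp(n, rate = spec$appearance_rate)
      birth <- 1L + floor(cumsum(gaps))
      birth <- pmin(birth, spec$n_frames)
      birth[1] <- 1L
    }
    death <- pmin(birth + life - 1L, spec$n_frames)
    censored <- (birth + life - 1L) > spec$n_frames | birth <= 1L
    # positions with minimum separation (greedy dart throwing)
    min_sep_px <- spec$min_separation / spec$px_size
    pos <- matrix(NA_real_, n, 2)
    margin <- 8
    for (i in seq_len(n)) {
      for (try in 1:200) {
        cand <- c(stats::runif(1, margin, shp[1] - margin),
                  stats::runif(1, margin, shp[2] - margin))
        # adhesions overlapping in time (with a small guard, so a newcomer
        # never lands where another just died and confuses gap-closing
        # trackers) constrain placement
        guard <- 3L
        live <- which(!is.na(pos[, 1]) & birth <= death[i] + guard &
                        death >= birth[i] - guard)
        if (length(live) == 0 ||
            min(sqrt((pos[live, 1] - cand[1])^2 + (pos[live, 2] - cand[2])^2)) >=
              min_sep_px) break
      }
      pos[i, ] <- cand
    }
    area <- spec$area_mean * stats::rgamma(n, shape = 6, rate = 6)
    aspect <- exp(stats::rnorm(n, log(2), 0.25))
    phi <- stats::runif(n, 0, pi)
    a_um <- sqrt(area * aspect / pi)   # semi-major
    b_um <- a_um / aspect
    frames <- vector("list", spec$n_frames)
    area_px <- rep(NA_real_, n)
    for (t in if (render) seq_len(spec$n_frames) else integer(0)) {
      img <- matrix(0, shp[1], shp[2])
      for (i in which(birth <= t & death >= t)) {
        res <- render_ellipse_patch(img, pos[i, 1], pos[i, 2],
                                    a_um[i] / spec$px_size,
                                    b_um[i] / spec$px_size,
                                    phi[i], spec$peak_intensity)
        img <- res$img
        if (is.na(area_px[i])) area_px[i] <- res$n_px
      }
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(prod(shp), sd = spec$noise_sd),
                            shp[1], shp[2])
      frames[[t]] <- img
    }
    truth <- data.frame(
      track_id = seq_len(n),
      birth_frame = birth, death_frame = death,
      lifetime_min = (death - birth + 1L) * spec$frame_interval,
      x_um = (pos[, 1] - 1) * spec$px_size,
      y_um = (pos[, 2] - 1) * spec$px_size,
      area_um2 = if (render) area_px * spec$px_size^2 else area * NA_real_,
      length_um = 2 * a_um,
      censored = censored)
    list(frames = if (render) frames else NULL, truth = truth, spec = spec)
  })
}
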