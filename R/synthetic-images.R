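#' Specification of synthetic substrate bead images
#'
#' Emulates fluorescent marker beads imaged at the hydrogel surface: beads
#' rendered as 2D Gaussian spots (PSF truncated at 4 sigma) over a dark
#' background with additive Gaussian read noise.  Bead density and noise are
#' package defaults chosen to emulate typical epifluorescence traction-force
#' recordings; they are not derived from any particular dataset.
#'
#' @param image_shape image size in px (length 1 or 2).
#' @param px_size pixel calibration, um/px.
#' @param bead_density beads per um^2.
#' @param psf_sigma spot standard deviation, px.
#' @param peak_intensity peak counts per bead.
#' @param noise_sd additive Gaussian noise sd, counts.
#' @param seed integer seed.
#' @return object of class `bead_image_spec`.
#' @export
bead_image_spec <- function(image_shape, px_size, bead_density = 0.05,
                            psf_sigma = 1.5, peak_intensity = 1000,
                            noise_sd = 10, seed = 1L) {
  if (length(image_shape) == 1) image_shape <- rep(image_shape, 2)
  if (px_size <= 0) stop_invalid("px_size must be > 0")
  if (psf_sigma <= 0) stop_invalid("psf_sigma must be > 0")
  if (bead_density <= 0) stop_invalid("bead_density must be > 0")
  structure(list(image_shape = as.integer(image_shape), px_size = px_size,
                 bead_density = bead_density, psf_sigma = psf_sigma,
                 peak_intensity = peak_intensity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "bead_image_spec")
}

## Render Gaussian spots at sub-pixel positions (1-based px coordinates).
## PSF truncated at 4 sigma.  Returns a numeric matrix of counts.
render_spots <- function(shape, pos_px, sigma, intensity) {
  img <- matrix(0, shape[1], shape[2])
  if (NROW(pos_px) == 0) return(img)
  if (length(intensity) == 1) intensity <- rep(intensity, nrow(pos_px))
  r <- ceiling(4 * sigma)
  for (b in seq_len(nrow(pos_px))) {
    cx <- pos_px[b, 1]; cy <- pos_px[b, 2]
    i0 <- max(1L, floor(cx) - r); i1 <- min(shape[1], floor(cx) + r + 1L)
    j0 <- max(1L, floor(cy) - r); j1 <- min(shape[2], floor(cy) + r + 1L)
    if (i0 > i1 || j0 > j1) next
    gi <- exp(-((i0:i1 - cx)^2) / (2 * sigma^2))
    gj <- exp(-((j0:j1 - cy)^2) / (2 * sigma^2))
    img[i0:i1, j0:j1] <- img[i0:i1, j0:j1] + intensity[b] * outer(gi, gj)
  }
  img
}

#' Generate a reference/stressed bead image pair
#'
#' Draws bead positions uniformly (count = `round(density * area)`), renders
#' the reference image, then renders the same beads displaced by the supplied
#' displacement field (bilinearly interpolated at each bead) for the stressed
#' image.  Additive Gaussian noise is applied independently to both images.
#'
#' @param spec a [bead_image_spec].
#' @param displacement a [vector_field] covering the image, units `"px"` or
#'   `"um"` (converted using `spec$px_size`).  `NULL` for zero displacement.
#' @return list with `reference`, `stressed` (count matrices), and
#'   `beads_px` (true bead positions, px).
#' @export
gen_bead_pair <- function(spec, displacement = NULL) {
  stopifnot(inherits(spec, "bead_image_spec"))
  shp <- spec$image_shape
  area_um2 <- prod(shp) * spec$px_size^2
  n_beads <- round(spec$bead_density * area_um2)
  with_seed(derive_seed(spec$seed, "bead_pair"), {
    pos <- cbind(stats::runif(n_beads, 1, shp[1]),
                 stats::runif(n_beads, 1, shp[2]))
    ref <- render_spots(shp, pos, spec$psf_sigma, spec$peak_intensity)
    if (is.null(displacement)) {
      dis <- matrix(0, n_beads, 2)
    } else {
      fld <- if (displacement$units == "um") {
        displacement$px_size <- displacement$px_size %||% spec$px_size
        convert_units(displacement, "px")
      } else displacement
      # node positions are in um; bead positions in px
      gx <- fld$x / spec$px_size + 1
      gy <- fld$y / spec$px_size + 1
      xi <- 1 + (pos[, 1] - gx[1]) / (gx[2] - gx[1])
      yi <- 1 + (pos[, 2] - gy[1]) / (gy[2] - gy[1])
      dis <- cbind(bilinear(fld$u, xi, yi), bilinear(fld$v, xi, yi))
    }
    str <- render_spots(shp, pos + dis, spec$psf_sigma, spec$peak_intensity)
    if (spec$noise_sd > 0) {
      ref <- ref + matrix(stats::rnorm(prod(shp), sd = spec$noise_sd), shp[1], shp[2])
      str <- str + matrix(stats::rnorm(prod(shp), sd = spec$noise_sd), shp[1], shp[2])
    }
    list(reference = ref, stressed = str, beads_px = pos)
  })
}

#' Generate a texture movie advected by a velocity field
#'
#' A smooth random texture is warped frame by frame by the cumulative
#' displacement of a (static) velocity field, emulating a phase-contrast
#' recording of a moving monolayer for PIV testing.  Optionally, a migration
#' front restricts the texture to `x <= front` with the front advancing at
#' `front_speed` so sheet-speed estimators can be tested on the same movie.
#'
#' @param field a [vector_field] in um/hr defining the motion (interpolated
#'   over the image), or a [field_spec] (realized internally).
#' @param n_frames number of frames (>= 2).
#' @param dt_min frame interval, minutes.
#' @param px_size pixel calibration, um/px.
#' @param image_shape image size in px; defaults to the field's extent.
#' @param texture_sigma_px smoothing scale of the random texture, px.
#' @param front_x0_um,front_speed_um_hr optional migration front: initial
#'   position and advance speed of the monolayer edge along x.
#' @param noise_sd additive image noise (fraction of texture contrast).
#' @param seed integer seed.
#' @return list with `frames` (list of matrices), `masks` (logical matrices or
#'   `NULL`), `field` (the ground-truth [vector_field]), `px_size`, `dt_min`.
#' @export
gen_texture_movie <- function(field, n_frames = 3L, dt_min = 10,
                              px_size = 1, image_shape = NULL,
                              texture_sigma_px = 2,
                              front_x0_um = NULL, front_speed_um_hr = 0,
                              noise_sd = 0.02, seed = 1L) {
  if (inherits(field, "field_spec")) field <- gen_velocity_field(field)
  stopifnot(inherits(field, "vector_field"), n_frames >= 2)
  if (is.null(image_shape)) {
    image_shape <- c(round(max(field$x) / px_size) + 1,
                     round(max(field$y) / px_size) + 1)
  }
  n1 <- image_shape[1]; n2 <- image_shape[2]
  with_seed(derive_seed(seed, "texture_movie"), {
    tex <- gauss_smooth_periodic(matrix(stats::rnorm(n1 * n2), n1, n2),
                                 texture_sigma_px)
    tex <- (tex - min(tex)) / diff(range(tex))
    # velocity (um/hr) interpolated at each pixel, in px/frame
    px_x <- (seq_len(n1) - 1) * px_size
    px_y <- (seq_len(n2) - 1) * px_size
    dgx <- if (length(field$x) > 1) diff(field$x[1:2]) else 1
    dgy <- if (length(field$y) > 1) diff(field$y[1:2]) else 1
    xi <- 1 + (matrix(px_x, n1, n2) - field$x[1]) / dgx
    yi <- 1 + (matrix(px_y, n1, n2, byrow = TRUE) - field$y[1]) / dgy
    upx <- bilinear(field$u, xi, yi) * (dt_min / 60) / px_size
    vpx <- bilinear(field$v, xi, yi) * (dt_min / 60) / px_size
    I <- matrix(seq_len(n1), n1, n2); J <- matrix(seq_len(n2), n1, n2, byrow = TRUE)
    frames <- vector("list", n_frames)
    masks <- if (!is.null(front_x0_um)) vector("list", n_frames) else NULL
    for (t in seq_len(n_frames)) {
      s <- t - 1
      fr <- bilinear(tex, I - s * upx, J - s * vpx)
      if (!is.null(front_x0_um)) {
        front <- front_x0_um + front_speed_um_hr * s * dt_min / 60
        m <- matrix(px_x, n1, n2) <= front
        fr <- fr * m + 0.05
        masks[[t]] <- m
      }
      if (noise_sd > 0)
        fr <- fr + matrix(stats::rnorm(n1 * n2, sd = noise_sd), n1, n2)
      frames[[t]] <- fr
    }
    list(frames = frames, masks = masks, field = field,
         px_size = px_size, dt_min = dt_min)
  })
}
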