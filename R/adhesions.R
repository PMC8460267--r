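#' Segment focal adhesions in one fluorescence frame
#'
#' Background is estimated by a large-scale Gaussian filter and subtracted;
#' pixels above `threshold_k` times the robust noise sd (MAD) of the
#' background-subtracted frame are foreground; 4-connected components with
#' area >= `min_area` are kept.  Per component the intensity-weighted
#' centroid and the major-axis length (from second moments,
#' ellipse-equivalent) are reported; the area is measured at half the
#' component's robust peak intensity (FWHM footprint), which undoes the
#' PSF skirt that the detection threshold necessarily includes.
#'
#' @param frame numeric matrix (single channel).
#' @param px_size pixel calibration, um/px.
#' @param background_scale background filter scale, px.
#' @param min_area minimum adhesion area, um^2.
#' @param threshold_k detection threshold in noise sd units (default 3).
#' @return data.frame with one row per adhesion: `x_um`, `y_um`, `area_um2`,
#'   `length_um`, `mean_intensity`.
#' @export
segment_adhesions <- function(frame, px_size = 0.1, background_scale = 20,
                              min_area = 0.25, threshold_k = 3) {
  if (max(frame) >= 65535) warning("frame appears saturated; proceeding")
  # background kernels are large: smooth spectrally (frames are dark at the
  # border, so periodic wrap is immaterial for the background estimate)
  bg <- gauss_smooth_periodic(frame, background_scale / 2)
  res <- frame - bg
  noise_sd <- stats::mad(as.vector(res))
  if (noise_sd == 0) noise_sd <- stats::sd(as.vector(res))
  mask <- res > threshold_k * noise_sd
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), length_um = numeric(0),
                      mean_intensity = numeric(0)))
  px_area <- tabulate(lab[lab > 0], nbins = n)
  keep <- which(px_area * px_size^2 >= min_area)
  if (length(keep) == 0)
    return(data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), length_um = numeric(0),
                      mean_intensity = numeric(0)))
  rows <- lapply(keep, function(k) {
    pix <- which(lab == k, arr.ind = TRUE)
    w <- res[pix]
    w[w < 0] <- 0
    # area at half the object's (robust) peak: for sharp adhesions blurred
    # by the PSF this recovers the physical footprint, where the detection
    # threshold itself would count the blurred skirt
    half <- 0.5 * stats::quantile(w, 0.95, names = FALSE)
    n_half <- sum(w >= half)
    tw <- sum(w)
    cx <- sum(w * pix[, 1]) / tw; cy <- sum(w * pix[, 2]) / tw
    # ellipse-equivalent major axis from weighted second moments
    mxx <- sum(w * (pix[, 1] - cx)^2) / tw + 1 / 12
    myy <- sum(w * (pix[, 2] - cy)^2) / tw + 1 / 12
    mxy <- sum(w * (pix[, 1] - cx) * (pix[, 2] - cy)) / tw
    l1 <- (mxx + myy) / 2 + sqrt(((mxx - myy) / 2)^2 + mxy^2)
    data.frame(x_um = (cx - 1) * px_size, y_um = (cy - 1) * px_size,
               area_um2 = n_half * px_size^2,
               length_um = 4 * sqrt(l1) * px_size,
               mean_intensity = mean(frame[pix]))
  })
  do.call(rbind, rows)
}

#' Track focal adhesions across frames
#'
#' Greedy nearest-neighbour frame-to-frame linking under a distance gate,
#' with gap closing over up to `max_gap` missed frames.  Focal adhesions are
#' nearly stationary, so a tight gate suffices and keeps the linker
#' auditable.  Tracks touching the first or last frame are flagged censored
#' (their observed lifetime truncates the true one).
#'
#' @param detections list (one element per frame) of data.frames as returned
#'   by [segment_adhesions].
#' @param max_link_dist maximum centroid displacement per frame, um.
#' @param max_gap maximum number of missed frames bridged (default 1).
#' @param frame_interval frame interval, minutes.
#' @return object of class `fa_tracks`: data.frame `tracks` (one row per
#'   track: `track_id`, `birth_frame`, `death_frame`, `lifetime_min`,
#'   `mean_area_um2`, `mean_length_um`, `x_um`, `y_um`, `censored`) plus
#'   `detections` with track assignments.
#' @export
track_adhesions <- function(detections, max_link_dist = 2, max_gap = 1L,
                            frame_interval = 2) {
  if (max_link_dist <= 0) stop_invalid("max_link_dist must be > 0")
  nf <- length(detections)
  if (nf == 0)
    return(structure(list(tracks = data.frame(), detections = data.frame()),
                     class = "fa_tracks"))
  det <- do.call(rbind, lapply(seq_len(nf), function(t) {
    d <- detections[[t]]
    if (is.null(d) || nrow(d) == 0) return(NULL)
    cbind(frame = t, d)
  }))
  if (is.null(det))
    return(structure(list(tracks = data.frame(), detections = data.frame()),
                     class = "fa_tracks"))
  det$track <- NA_integer_
  next_id <- 0L
  # active tracks: id, last frame, last position
  act_id <- integer(0); act_t <- integer(0)
  act_x <- numeric(0); act_y <- numeric(0)
  for (t in seq_len(nf)) {
    cur <- which(det$frame == t)
    if (length(cur) == 0) next
    live <- which(t - act_t <= max_gap + 1L)
    if (length(live) > 0 && length(cur) > 0) {
      # greedy: link closest pairs first, gate scaled by the gap length
      dx <- outer(act_x[live], det$x_um[cur], `-`)
      dy <- outer(act_y[live], det$y_um[cur], `-`)
      dist <- sqrt(dx^2 + dy^2)
      gate <- max_link_dist * (t - act_t[live])
      ord <- order(dist)
      used_a <- logical(length(live)); used_c <- logical(length(cur))
      gmax <- max(gate)
      for (o in ord) {
        if (dist[o] > gmax) break
        ai <- (o - 1) %% length(live) + 1
        ci <- (o - 1) %/% length(live) + 1
        if (used_a[ai] || used_c[ci]) next
        if (dist[ai, ci] > gate[ai]) next
        used_a[ai] <- TRUE; used_c[ci] <- TRUE
        id <- act_id[live[ai]]
        det$track[cur[ci]] <- id
        act_t[live[ai]] <- t
        act_x[live[ai]] <- det$x_um[cur[ci]]
        act_y[live[ai]] <- det$y_um[cur[ci]]
      }
    }
    new <- cur[is.na(det$track[cur])]
    for (ci in new) {
      next_id <- next_id + 1L
      det$track[ci] <- next_id
      act_id <- c(act_id, next_id); act_t <- c(act_t, t)
      act_x <- c(act_x, det$x_um[ci]); act_y <- c(act_y, det$y_um[ci])
    }
  }
  sp <- split(det, det$track)
  tracks <- do.call(rbind, lapply(sp, function(g) {
    data.frame(track_id = g$track[1],
               birth_frame = min(g$frame), death_frame = max(g$frame),
               lifetime_min = (max(g$frame) - min(g$frame) + 1L) * frame_interval,
               mean_area_um2 = mean(g$area_um2),
               mean_length_um = mean(g$length_um),
               x_um = mean(g$x_um), y_um = mean(g$y_um),
               censored = min(g$frame) <= 1L || max(g$frame) >= nf)
  }))
  rownames(tracks) <- NULL
  structure(list(tracks = tracks, detections = det,
                 frame_interval = frame_interval, n_frames = nf),
            class = "fa_tracks")
}

#' @export
print.fa_tracks <- function(x, ...) {
  cat(sprintf("<fa_tracks> %d tracks over %d frames (dt %.3g min)\n",
              nrow(x$tracks), x$n_frames, x$frame_interval))
  if (nrow(x$tracks) > 0)
    cat(sprintf("  censored: %d; mean lifetime (uncensored) %.4g min\n",
                sum(x$tracks$censored),
                mean(x$tracks$lifetime_min[!x$tracks$censored])))
  invisible(x)
}

#' Cell surface contact area and adhesion density
#'
#' Segments the diffuse cytoplasmic signal (largest connected supra-threshold
#' region after hole filling) and reports its area together with the
#' adhesion density `n_adhesions / area`.
#'
#' @param frame numeric matrix.
#' @param cytoplasm_threshold relative threshold in (0, 1) on the intensity
#'   range.
#' @param px_size pixel calibration, um/px.
#' @param n_adhesions adhesion count in the frame (for the density; may be
#'   `NA`).
#' @return list with `area_um2`, `density_per_um2`, `mask`.
#' @export
contact_area <- function(frame, cytoplasm_threshold = 0.2, px_size = 0.1,
                         n_adhesions = NA_integer_) {
  if (max(frame) <= 0) stop_data("no supra-threshold pixels: blank frame")
  thr <- min(frame) + cytoplasm_threshold * (max(frame) - min(frame))
  mask <- frame >= thr
  if (!any(mask)) stop_data("no supra-threshold pixels")
  lab <- label_components(mask)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  mask <- fill_holes(lab == which.max(sizes))
  area <- sum(mask) * px_size^2
  list(area_um2 = area,
       density_per_um2 = if (is.na(n_adhesions)) NA_real_ else n_adhesions / area,
       mask = mask)
}

#' Lifetime summary over focal-adhesion tracks
#'
#' Mean, sd and count of track lifetimes.  Censored tracks (touching the
#' movie start or end) are excluded by default, since their observed
#' lifetimes truncate the true ones and bias the mean low.
#'
#' @param tracks an `fa_tracks` object (or its `tracks` data.frame).
#' @param exclude_censored drop censored tracks (default `TRUE`).
#' @return list with `mean_min`, `sd_min` (`NA` when n = 1), `n`, and the
#'   per-track table used.
#' @export
lifetime_summary <- function(tracks, exclude_censored = TRUE) {
  tab <- if (inherits(tracks, "fa_tracks")) tracks$tracks else tracks
  if (is.null(tab) || nrow(tab) == 0) stop_data("no tracks")
  if (exclude_censored) tab <- tab[!tab$censored, , drop = FALSE]
  if (nrow(tab) == 0)
    stop_data("all tracks are censored; rerun with exclude_censored = FALSE")
  list(mean_min = mean(tab$lifetime_min),
       sd_min = if (nrow(tab) > 1) stats::sd(tab$lifetime_min) else NA_real_,
       n = nrow(tab), tracks = tab)
}
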