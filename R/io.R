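#' Read and write multi-frame 16-bit TIFF movies
#'
#' Frames are numeric count matrices; on write they are scaled by 1/65535
#' and stored as 16-bit, so a round trip returns counts rounded to integers
#' and clamped to `[0, 65535]`.
#'
#' @param frames list of numeric matrices (or one matrix).
#' @param path file path.
#' @return `read_movie_tiff` returns a list of numeric matrices (counts).
#' @export
write_movie_tiff <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  norm <- lapply(frames, function(f) {
    f <- pmin(pmax(f, 0), 65535) / 65535
    f
  })
  tiff::writeTIFF(norm, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(path) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(imgs)) imgs <- list(imgs)
  lapply(imgs, function(f) f * 65535)
}

#' Write / read a vector field as CSV (x_um, y_um, u, v, quality)
#'
#' @param field a [vector_field]; `path` file path.
#' @param units units flag to restore on read.
#' @return `read_field_csv` returns a [vector_field].
#' @export
write_field_csv <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @param path CSV path.
#' @export
read_field_csv <- function(path, units = "um") {
  df <- utils::read.csv(path)
  xs <- sort(unique(df$x_um)); ys <- sort(unique(df$y_um))
  ix <- match(df$x_um, xs); iy <- match(df$y_um, ys)
  mk <- function(vals) {
    m <- matrix(NA_real_, length(xs), length(ys))
    m[cbind(ix, iy)] <- vals
    m
  }
  q <- mk(df$quality)
  vector_field(xs, ys, mk(df$u), mk(df$v), units = units,
               quality = if (all(is.na(q))) NULL else q)
}

#' Write a stress field as CSV
#' @param stress a [stress_field]; `path` file path.
#' @export
write_stress_csv <- function(stress, path) {
  utils::write.csv(as.data.frame(stress), path, row.names = FALSE)
  invisible(path)
}

#' Write a correlation curve as CSV plus a JSON summary
#'
#' @param curve a [correlation_curve].
#' @param path CSV path; the JSON summary replaces the extension with
#'   `.json`.
#' @param mode descriptor recorded in the summary (e.g. `"velocity"`).
#' @export
write_correlation <- function(curve, path, mode = "velocity") {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  summary_path <- sub("\\.csv$", ".json", path)
  jsonlite::write_json(
    list(correlation_length_um = curve$correlation_length,
         threshold = curve$threshold, mode = mode,
         censored_at_um = if (is.na(curve$correlation_length))
           max(curve$r) else NULL),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
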