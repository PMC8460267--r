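#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic sub-seed derivation: every stochastic operation draws its own
## stream from (seed, label) so sub-generators stay independent and reordering
## one stage never perturbs another.  Splitmix-style integer mixing, kept below
## 2^31 so the result is a valid R seed.
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 2654435761 + h * 40503 + 12345) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_invalid <- function(...) {
  stop(structure(class = c("sheetmech_invalid_parameter", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("sheetmech_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

## ---- FFT helpers (base stats::fft on matrices) ----

fft2 <- function(x, inverse = FALSE) stats::fft(x, inverse = inverse)

ifft2_real <- function(x) Re(stats::fft(x, inverse = TRUE)) / length(x)

## Angular frequency along one axis for an n-point grid with spacing d,
## in fftfreq order (0, +, ..., -).
fft_wavenumbers <- function(n, d) {
  i <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * i / (n * d)
}

## Periodic convolution of a matrix with an isotropic Gaussian kernel of
## standard deviation `sigma` grid units.  Done spectrally: the transfer
## function of a sampled Gaussian is exp(-sigma^2 k^2 / 2).
gauss_smooth_periodic <- function(x, sigma) {
  if (sigma <= 0) return(x)
  n1 <- nrow(x); n2 <- ncol(x)
  k1 <- fft_wavenumbers(n1, 1)
  k2 <- fft_wavenumbers(n2, 1)
  h <- outer(exp(-0.5 * sigma^2 * k1^2), exp(-0.5 * sigma^2 * k2^2))
  ifft2_real(fft2(x) * h)
}

## Cross-correlation sums over all integer offsets via zero-padded FFT.
## Returns a (2*n1-1) x (2*n2-1) matrix S with S[dx + n1, dy + n2] =
## sum_{x} a[x] * b[x + (dx,dy)] for offsets dx in -(n1-1)..(n1-1).
## NA values must be pre-masked to 0 by the caller.
xcorr_all_lags <- function(a, b) {
  n1 <- nrow(a); n2 <- ncol(a)
  m1 <- 2L * n1; m2 <- 2L * n2
  pa <- matrix(0, m1, m2); pa[1:n1, 1:n2] <- a
  pb <- matrix(0, m1, m2); pb[1:n1, 1:n2] <- b
  s <- ifft2_real(Conj(fft2(pa)) * fft2(pb))
  # lag (dx, dy) lives at index (dx mod m1) + 1
  idx1 <- c(m1 - (n1 - 1):1 + 1L, 1L, 1L + 1:(n1 - 1))
  idx2 <- c(m2 - (n2 - 1):1 + 1L, 1L, 1L + 1:(n2 - 1))
  s[idx1, idx2]
}

## ---- interpolation ----

## Bilinear interpolation of matrix z (rows ~ x, cols ~ y) at continuous
## 1-based fractional indices (xi, yi).  Clamped at the borders.
bilinear <- function(z, xi, yi) {
  n1 <- nrow(z); n2 <- ncol(z)
  dims <- dim(xi)
  xi <- pmin(pmax(as.vector(xi), 1), n1); yi <- pmin(pmax(as.vector(yi), 1), n2)
  x0 <- pmin(floor(xi), n1 - 1L); y0 <- pmin(floor(yi), n2 - 1L)
  fx <- xi - x0; fy <- yi - y0
  z00 <- z[cbind(x0, y0)];     z10 <- z[cbind(x0 + 1, y0)]
  z01 <- z[cbind(x0, y0 + 1)]; z11 <- z[cbind(x0 + 1, y0 + 1)]
  out <- z00 * (1 - fx) * (1 - fy) + z10 * fx * (1 - fy) +
    z01 * (1 - fx) * fy + z11 * fx * fy
  if (!is.null(dims)) dim(out) <- dims
  out
}

## ---- connected components (iterative label propagation, vectorized) ----

## Label 4-connected foreground components of a logical matrix.  Labels are
## renumbered 1..n_components; background is 0.
label_components <- function(mask) {
  n1 <- nrow(mask); n2 <- ncol(mask)
  lab <- matrix(0L, n1, n2)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(lab)
  labv <- matrix(0, n1, n2)
  labv[mask] <- which(mask)  # numeric for pmin with Inf
  labv[!mask] <- Inf
  repeat {
    new <- labv
    new[-1, ]  <- pmin(new[-1, ],  labv[-n1, ])
    new[-n1, ] <- pmin(new[-n1, ], labv[-1, ])
    new[, -1]  <- pmin(new[, -1],  labv[, -n2])
    new[, -n2] <- pmin(new[, -n2], labv[, -1])
    new[!mask] <- Inf
    if (identical(new, labv)) break
    labv <- new
  }
  ids <- sort(unique(labv[mask]))
  lab[mask] <- match(labv[mask], ids)
  lab
}

## Fill holes: background pixels not connected to the image border become
## foreground.
fill_holes <- function(mask) {
  bg <- !mask
  lab <- label_components(bg)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- setdiff(border, 0L)
  mask | (bg & !(lab %in% border))
}

rel_l2 <- function(est, truth) {
  sqrt(sum((est - truth)^2, na.rm = TRUE)) / sqrt(sum(truth^2, na.rm = TRUE))
}
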