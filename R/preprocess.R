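#' 4D BOLD series on a volume grid
#'
#' Stores the series as a time x voxel matrix in array (column-major) voxel
#' order, with the repetition time in seconds.
#'
#' @param data numeric matrix, T x prod(grid$shape), or a 4D array.
#' @param grid a `volume_grid`.
#' @param tr_seconds repetition time in seconds (> 0).
#' @return an object of class `bold4d`.
#' @export
bold4d <- function(data, grid, tr_seconds) {
  if (is.array(data) && length(dim(data)) == 4L) {
    stopifnot(identical(dim(data)[1:3], as.integer(grid$shape)))
    nt <- dim(data)[4]
    data <- t(matrix(data, nrow = prod(grid$shape), ncol = nt))
  }
  data <- as.matrix(data)
  if (ncol(data) != n_voxels(grid)) {
    stop("data column count does not match the grid voxel count")
  }
  if (nrow(data) < 8L) stop("BOLD series needs at least 8 time points")
  if (!is.finite(tr_seconds) || tr_seconds <= 0) stop("tr_seconds must be > 0")
  if (anyNA(data) || !all(is.finite(range(data)))) {
    stop("BOLD data contains non-finite values")
  }
  structure(list(data = data, grid = grid, tr_seconds = as.numeric(tr_seconds)),
            class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  cat(sprintf("bold4d: %d time points (TR %.3g s) on ", nrow(x$data),
              x$tr_seconds))
  print(x$grid)
  invisible(x)
}

#' Nyquist frequency of a BOLD series
#' @param bold a `bold4d`.
#' @export
nyquist_hz <- function(bold) 1 / (2 * bold$tr_seconds)

linear_detrend <- function(mat) {
  nt <- nrow(mat)
  tt <- seq_len(nt) - (nt + 1) / 2
  mat <- sweep(mat, 2L, colMeans(mat), `-`)
  slope <- crossprod(tt, mat) / sum(tt^2)
  mat - outer(tt, as.vector(slope))
}

#' Temporal band-pass filter
#'
#' Frequency-domain ideal filter: the series is (optionally) linearly
#' detrended, transformed by FFT, DFT bins with frequency outside
#' `[low_hz, high_hz]` are zeroed (the 0 Hz mean always is), and the series
#' is transformed back. Output length equals input length.
#'
#' @param bold a `bold4d`.
#' @param low_hz,high_hz pass-band edges in Hz; defaults 0.01 and 0.08.
#' @param detrend remove a linear trend first (default TRUE).
#' @return a new `bold4d`; the input is not modified.
#' @export
bandpass_filter <- function(bold, low_hz = 0.01, high_hz = 0.08,
                            detrend = TRUE) {
  stopifnot(inherits(bold, "bold4d"))
  nyq <- nyquist_hz(bold)
  if (!(low_hz >= 0 && low_hz < high_hz)) {
    stop("need 0 <= low_hz < high_hz")
  }
  if (high_hz > nyq + 1e-12) {
    stop(sprintf("high_hz (%g Hz) exceeds the Nyquist frequency %g Hz for TR %g s",
                 high_hz, nyq, bold$tr_seconds))
  }
  x <- bold$data
  if (detrend) x <- linear_detrend(x)
  nt <- nrow(x)
  f <- bin_frequencies(nt, bold$tr_seconds)
  keep <- f >= low_hz - 1e-12 & f <= high_hz + 1e-12
  keep[1] <- FALSE # DC always removed
  ft <- stats::mvfft(x)
  ft[!keep, ] <- 0
  out <- Re(stats::mvfft(ft, inverse = TRUE)) / nt
  bold4d(out, bold$grid, bold$tr_seconds)
}

# Physical frequency of each DFT bin (aliased, so bin k and N-k agree)
bin_frequencies <- function(nt, tr) {
  k <- 0:(nt - 1)
  pmin(k, nt - k) / (nt * tr)
}

gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  r <- ceiling(6 * sigma_vox)
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Banded (truncated, zero-padded) 1D convolution matrix for one axis
conv_matrix <- function(n, kernel) {
  r <- (length(kernel) - 1L) / 2L
  M <- matrix(0, n, n)
  for (off in (-r):r) {
    i <- seq_len(n)
    j <- i + off
    ok <- j >= 1 & j <= n
    M[cbind(i[ok], j[ok])] <- kernel[off + r + 1L]
  }
  M
}

# Separable 3D convolution of an (nx, ny, nz * nframes) stack via one GEMM
# per tensor mode; frames share the x/y/z kernels.
separable_conv3d <- function(arr4, Kx, Ky, Kz) {
  d <- dim(arr4)
  nf <- if (length(d) == 4L) d[4] else 1L
  dim(arr4) <- c(d[1], d[2], d[3] * nf)
  a <- Kx %*% matrix(arr4, d[1], d[2] * d[3] * nf)
  dim(a) <- c(d[1], d[2], d[3] * nf)
  a <- aperm(a, c(2, 1, 3))
  a <- Ky %*% matrix(a, d[2], d[1] * d[3] * nf)
  dim(a) <- c(d[2], d[1], d[3], nf)
  a <- aperm(a, c(3, 2, 1, 4))
  a <- Kz %*% matrix(a, d[3], d[1] * d[2] * nf)
  dim(a) <- c(d[3], d[1], d[2], nf)
  a <- aperm(a, c(2, 3, 1, 4))
  if (length(d) == 4L) a else array(a, d)
}

# Mask-aware renormalized Gaussian smoothing of a (shape, nframes) stack;
# returns an array of the same dim. Shared by spatial_smooth and the
# spectral ALFF path.
spatial_smooth_frames <- function(frames, fwhm_mm, grid, mask = NULL) {
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  vs <- voxel_size(grid)
  Ks <- lapply(1:3, function(a) {
    conv_matrix(grid$shape[a], gaussian_kernel_1d(sigma_mm / vs[a]))
  })
  if (is.null(mask)) {
    return(separable_conv3d(frames, Ks[[1]], Ks[[2]], Ks[[3]]))
  }
  denom <- separable_conv3d(array(as.numeric(mask), dim = grid$shape),
                            Ks[[1]], Ks[[2]], Ks[[3]])
  denom[denom <= 0 | !mask] <- NA
  sm <- separable_conv3d(frames * as.vector(mask),
                         Ks[[1]], Ks[[2]], Ks[[3]]) / as.vector(denom)
  sm[is.na(sm)] <- 0
  sm
}

#' Isotropic Gaussian spatial smoothing
#'
#' Convolves each volume with a Gaussian of the given full width at half
#' maximum, sigma = fwhm / (2 * sqrt(2 * log(2))) per axis in mm, converted to
#' voxel units from the grid affine. Inside a mask the convolution is
#' renormalized (divided by the smoothed mask) so edge voxels are not diluted
#' by out-of-mask zeros; voxels outside the mask are set to zero.
#'
#' @param x a 3D numeric array (scalar map) or a `bold4d`.
#' @param fwhm_mm full width at half maximum in mm (>= 0; 0 is the identity).
#' @param grid the `volume_grid` (taken from `x` for a `bold4d`).
#' @param mask logical array; `NULL` (default) smooths over the whole field
#'   of view with plain zero-padded boundaries.
#' @return same type as `x`; inputs are not modified.
#' @export
spatial_smooth <- function(x, fwhm_mm, grid = NULL, mask = NULL) {
  if (!is.finite(fwhm_mm) || fwhm_mm < 0) stop("fwhm_mm must be >= 0")
  is_bold <- inherits(x, "bold4d")
  if (is_bold) grid <- x$grid
  if (is.null(grid)) stop("grid is required for array input")
  if (fwhm_mm == 0) return(x)
  if (!is.null(mask)) stopifnot(identical(dim(mask), grid$shape))
  if (is_bold) {
    nt <- nrow(x$data)
    arr <- array(t(x$data), dim = c(grid$shape, nt))
    sm <- spatial_smooth_frames(arr, fwhm_mm, grid, mask)
    out <- t(matrix(sm, nrow = n_voxels(grid), ncol = nt))
    return(bold4d(out, grid, x$tr_seconds))
  }
  stopifnot(identical(dim(x), grid$shape))
  array(spatial_smooth_frames(x, fwhm_mm, grid, mask), dim = grid$shape)
}
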