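#' Voxel-wise amplitude of low-frequency fluctuations (ALFF)
#'
#' Each voxel's series is transformed to the frequency domain by FFT; the
#' one-sided amplitude spectrum is amp_k = 2 |c_k| / N (so a single-bin
#' sinusoid of amplitude A has amp = A at its bin), and ALFF is the mean of
#' amp_k over the DFT bins whose frequency f_k = k / (N * TR), k >= 1, falls
#' inside the band (both edges inclusive; the 0 Hz and Nyquist bins are
#' always excluded).
#'
#' @param bold a `bold4d`; conventionally already band-pass filtered to the
#'   same band, which leaves the in-band bins untouched.
#' @param band_hz length-2 numeric, pass band in Hz; default `c(0.01, 0.08)`.
#' @return an `alff_map`: list with `values` (3D array, >= 0), `grid`,
#'   `band_hz`, `tr_seconds`, `standardized = FALSE`.
#' @export
compute_alff_map <- function(bold, band_hz = c(0.01, 0.08)) {
  stopifnot(inherits(bold, "bold4d"), length(band_hz) == 2)
  low <- band_hz[1]; high <- band_hz[2]
  nyq <- nyquist_hz(bold)
  if (low < 0 || low >= high || high > nyq + 1e-12) {
    stop(sprintf("band must lie within (0, %g] Hz (Nyquist for TR %g s)",
                 nyq, bold$tr_seconds))
  }
  nt <- nrow(bold$data)
  k_max <- ceiling(nt / 2) - 1L # one-sided bins 1..k_max, Nyquist excluded
  f <- (1:k_max) / (nt * bold$tr_seconds)
  inband <- which(f >= low - 1e-12 & f <= high + 1e-12)
  if (length(inband) == 0L) {
    stop(sprintf(
      "no DFT bin in band [%g, %g] Hz: bin spacing is %g Hz for N = %d, TR = %g s",
      low, high, 1 / (nt * bold$tr_seconds), nt, bold$tr_seconds))
  }
  ft <- stats::mvfft(bold$data)
  amp <- 2 * Mod(ft[1L + inband, , drop = FALSE]) / nt
  values <- array(colMeans(amp), dim = bold$grid$shape)
  structure(
    list(values = values, grid = bold$grid, band_hz = c(low, high),
         tr_seconds = bold$tr_seconds, standardized = FALSE),
    class = "alff_map"
  )
}

#' Standardize an ALFF map by its full-brain mean
#'
#' Divides every voxel by the mean ALFF over the brain mask, so the in-mask
#' mean of the result is exactly 1.
#'
#' @param alff an `alff_map`.
#' @param brain_mask logical array; defaults to the grid's brain mask.
#' @return a standardized `alff_map`.
#' @export
standardize_alff <- function(alff, brain_mask = NULL) {
  stopifnot(inherits(alff, "alff_map"))
  if (is.null(brain_mask)) brain_mask <- alff$grid$brain_mask
  stopifnot(identical(dim(brain_mask), alff$grid$shape))
  m <- mean(alff$values[brain_mask])
  if (!is.finite(m) || m <= 0) {
    stop("in-mask mean ALFF is not positive; cannot standardize")
  }
  alff$values <- alff$values / m
  alff$standardized <- TRUE
  alff
}

#' @export
print.alff_map <- function(x, ...) {
  cat(sprintf("alff_map (%s): band %.3g-%.3g Hz, TR %.3g s, mean in mask %.4g\n",
              if (x$standardized) "standardized" else "raw",
              x$band_hz[1], x$band_hz[2], x$tr_seconds,
              mean(x$values[x$grid$brain_mask])))
  invisible(x)
}

#' Full per-subject ALFF pipeline
#'
#' Applies the standard preprocessing order — spatial smoothing, temporal
#' band-pass filtering — then computes and standardizes the ALFF map.
#'
#' @param bold a `bold4d`.
#' @param band_hz pass band, default `c(0.01, 0.08)` Hz.
#' @param fwhm_mm smoothing kernel FWHM, default 8 mm (0 disables).
#' @param smooth_mask mask for renormalized smoothing; defaults to the brain
#'   mask.
#' @param detrend linear detrend before filtering.
#' @param standardize divide by the full-brain mean (default TRUE).
#' @param fast smooth only the in-band spectral frames instead of the full
#'   series. Spatial smoothing is one fixed linear operator applied per
#'   frame and the temporal DFT acts per voxel, so the two commute and the
#'   result is identical (to numerical precision) at a fraction of the
#'   cost; set `FALSE` to run the literal smooth-filter-transform chain.
#' @return an `alff_map`.
#' @export
alff_pipeline <- function(bold, band_hz = c(0.01, 0.08), fwhm_mm = 8,
                          smooth_mask = NULL, detrend = TRUE,
                          standardize = TRUE, fast = TRUE) {
  if (is.null(smooth_mask)) smooth_mask <- bold$grid$brain_mask
  if (fast) {
    alff <- alff_spectral_path(bold, band_hz, fwhm_mm, smooth_mask, detrend)
  } else {
    if (fwhm_mm > 0) bold <- spatial_smooth(bold, fwhm_mm, mask = smooth_mask)
    bold <- bandpass_filter(bold, band_hz[1], band_hz[2], detrend = detrend)
    alff <- compute_alff_map(bold, band_hz)
  }
  if (standardize) standardize_alff(alff) else alff
}

# detrend -> temporal FFT -> spatially smooth the in-band complex frames
# (real and imaginary parts separately) -> one-sided amplitude mean.
alff_spectral_path <- function(bold, band_hz, fwhm_mm, smooth_mask, detrend) {
  grid <- bold$grid
  nt <- nrow(bold$data)
  x <- if (detrend) linear_detrend(bold$data) else bold$data
  k_max <- ceiling(nt / 2) - 1L
  f <- (1:k_max) / (nt * bold$tr_seconds)
  inband <- which(f >= band_hz[1] - 1e-12 & f <= band_hz[2] + 1e-12)
  if (length(inband) == 0L) {
    stop(sprintf(
      "no DFT bin in band [%g, %g] Hz: bin spacing is %g Hz for N = %d, TR = %g s",
      band_hz[1], band_hz[2], 1 / (nt * bold$tr_seconds), nt,
      bold$tr_seconds))
  }
  ft <- stats::mvfft(x)[1L + inband, , drop = FALSE]
  if (fwhm_mm > 0) {
    K <- length(inband)
    frames <- array(cbind(Re(t(ft)), Im(t(ft))), dim = c(grid$shape, 2L * K))
    sm <- spatial_smooth_frames(frames, fwhm_mm, grid, smooth_mask)
    sm <- matrix(sm, nrow = n_voxels(grid))
    amp <- 2 * sqrt(sm[, 1:K, drop = FALSE]^2 +
                      sm[, K + (1:K), drop = FALSE]^2) / nt
    values <- array(rowMeans(amp), dim = grid$shape)
  } else {
    values <- array(colMeans(2 * Mod(ft) / nt), dim = grid$shape)
  }
  structure(
    list(values = values, grid = grid, band_hz = band_hz,
         tr_seconds = bold$tr_seconds, standardized = FALSE),
    class = "alff_map"
  )
}
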