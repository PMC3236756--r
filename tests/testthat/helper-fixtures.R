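# Shared fixtures: small grids, sinusoid BOLD builders, oracles.

tiny_grid <- function(shape = c(9, 9, 9), voxel_mm = 3, brain_mask = NULL) {
  grid_from_spacing(shape, voxel_mm, brain_mask = brain_mask)
}

# bold4d whose every voxel carries the same series
uniform_bold <- function(series, shape = c(3, 3, 1), tr = 2) {
  g <- tiny_grid(shape)
  bold4d(matrix(series, length(series), prod(shape)), g, tr)
}

# bold4d with independent N(0, sd) series per voxel
noise_bold <- function(nt, shape = c(4, 4, 2), tr = 2, sd = 1) {
  g <- tiny_grid(shape)
  bold4d(matrix(rnorm(nt * prod(shape), sd = sd), nt, prod(shape)), g, tr)
}

# O(N^2) direct DFT amplitude oracle: mean over in-band bins of 2|c_k|/N
alff_dft_oracle <- function(x, tr, band = c(0.01, 0.08)) {
  n <- length(x)
  k_max <- ceiling(n / 2) - 1L
  f <- (1:k_max) / (n * tr)
  bins <- which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12)
  tt <- 0:(n - 1)
  amps <- vapply(bins, function(k) {
    ck <- sum(x * exp(-2i * pi * k * tt / n))
    2 * Mod(ck) / n
  }, 0)
  mean(amps)
}

# Explicit residualize-then-correlate oracle for the across-subject GLM
covariance_t_oracle <- function(Y, seed, covariates) {
  n <- nrow(Y)
  Z <- cbind(1, covariates)
  P <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z)
  ys <- P %*% Y
  ss <- as.vector(P %*% seed)
  r <- as.vector(crossprod(ss, ys)) / sqrt(sum(ss^2) * colSums(ys^2))
  df <- n - 2 - ncol(covariates)
  r * sqrt(df) / sqrt(1 - r^2)
}

# stat_map holding given values on a fresh grid
toy_stat_map <- function(values, df = 28, shape = dim(values), ...) {
  g <- tiny_grid(shape)
  stat_map(array(values, dim = g$shape), g, df, ...)
}

# thresholded_map with prescribed significance masks (t set to +/- 2*t_crit)
toy_thresholded <- function(pos, neg, df = 28, alpha = 0.05) {
  stopifnot(!any(pos & neg))
  g <- tiny_grid(dim(pos))
  V <- prod(dim(pos))
  t_crit <- qt(1 - alpha / (2 * V), df)
  tv <- array(0, dim(pos))
  tv[pos] <- 2 * t_crit
  tv[neg] <- -2 * t_crit
  fwe_threshold(stat_map(tv, g, df), alpha)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
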