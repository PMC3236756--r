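#' Specification of a synthetic multi-subject resting-state cohort
#'
#' Defines the desk-scale study the generator emulates: a small centred grid
#' with a spherical brain mask, nine 6-mm seed regions (the canonical MNI
#' coordinates scaled to fit the field of view), WM and CSF compartments,
#' band-limited BOLD signals with planted temporal-correlation modules, an
#' across-subject amplitude model with an anti-correlated two-system
#' structure, site/sex/age nuisance effects, and structurally covarying
#' gray-matter maps.
#'
#' Amplitude model: per subject, system factors (h, l) are drawn from a
#' bivariate normal with unit SDs and correlation `amp_corr` (default -0.8);
#' each region's BOLD amplitude is
#' `amp_base * (1 + amp_loading * f + covariate effects + amp_noise_sd * e)`,
#' with f = h for DMN/TPN regions and f = l for sensory regions.
#' Temporal model: each region voxel's series shares its system's latent
#' band-limited signal in variance proportion `rho_time`; the DMN and TPN
#' latent signals are correlated at `dmn_tpn_temporal_corr`.
#'
#' @param shape,voxel_mm grid shape and isotropic voxel size.
#' @param brain_radius_mm radius of the spherical brain mask.
#' @param roi_scale factor applied to the canonical seed MNI coordinates so
#'   the spheres fit the grid (default 0.35).
#' @param roi_radius_mm seed sphere radius (default 6 mm).
#' @param wm_center,wm_radius,csf_center,csf_radius tissue compartment
#'   spheres (mm).
#' @param n_subjects,n_timepoints,tr_seconds cohort dimensions.
#' @param band_hz pass band of the planted signals.
#' @param rho_time variance share of the shared module signal in a region
#'   voxel's band-limited activity.
#' @param dmn_tpn_temporal_corr correlation planted between the DMN and TPN
#'   latent time courses (negative: anti-correlated).
#' @param amp_base,amp_loading,amp_corr,amp_noise_sd across-subject BOLD
#'   amplitude model (see above).
#' @param background_amp band-limited amplitude of non-region brain voxels
#'   (constant across subjects).
#' @param compartment_amp_sd subject SD of the WM/CSF amplitudes.
#' @param bold_noise_sd white temporal noise SD.
#' @param gm_base,gm_background,gm_loading,gm_corr,gm_noise_sd,tcv_sd
#'   gray-matter model: region GM loads on per-system structural factors
#'   (correlation `gm_corr`), everything is scaled by a subject total-volume
#'   factor with SD `tcv_sd`.
#' @param center_effect,sex_effect,age_effect_per_decade planted nuisance
#'   effects on BOLD amplitude (relative units).
#' @param n_centers,age_range phenotype structure.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(24, 24, 24), voxel_mm = 3,
                           brain_radius_mm = 34,
                           roi_scale = 0.35, roi_radius_mm = 6,
                           wm_center = c(0, 0, 0), wm_radius = 7,
                           csf_center = c(0, 12, -14), csf_radius = 6,
                           n_subjects = 60, n_timepoints = 150,
                           tr_seconds = 2, band_hz = c(0.01, 0.08),
                           rho_time = 0.5, dmn_tpn_temporal_corr = -0.6,
                           amp_base = 1, amp_loading = 0.18,
                           amp_corr = -0.8, amp_noise_sd = 0.05,
                           background_amp = 0.8, compartment_amp_sd = 0.1,
                           bold_noise_sd = 0.25,
                           gm_base = 1, gm_background = 0.5,
                           gm_loading = 0.15, gm_corr = 0,
                           gm_noise_sd = 0.1, tcv_sd = 0.05,
                           center_effect = 0.02, sex_effect = 0.01,
                           age_effect_per_decade = -0.01,
                           n_centers = 2, age_range = c(18, 60)) {
  stopifnot(abs(amp_corr) <= 1, abs(gm_corr) <= 1,
            abs(dmn_tpn_temporal_corr) <= 1,
            rho_time >= 0, rho_time <= 1,
            bold_noise_sd >= 0, amp_noise_sd >= 0, gm_noise_sd >= 0,
            n_subjects >= 2, n_timepoints >= 8)
  spec <- as.list(environment())
  class(spec) <- "synthetic_spec"
  spec
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "synthetic_spec: %d subjects, T = %d, TR = %g s, grid %s at %g mm\n  planted system amplitude correlation %.2f, temporal module share %.2f\n",
    x$n_subjects, x$n_timepoints, x$tr_seconds,
    paste(x$shape, collapse = "x"), x$voxel_mm, x$amp_corr, x$rho_time))
  invisible(x)
}

# In-band one-sided DFT bin indices (k >= 1, Nyquist excluded)
inband_bins <- function(nt, tr, band) {
  k_max <- ceiling(nt / 2) - 1L
  f <- (1:k_max) / (nt * tr)
  which(f >= band[1] - 1e-12 & f <= band[2] + 1e-12)
}

# Random-phase unit-variance band-limited spectra: K x m complex matrix of
# one-sided coefficients in "series FFT" units (|c| = A * N / 2 per bin,
# sum of bin variances = 1).
random_band_spectra <- function(nbins, m, nt) {
  amp <- sqrt(2 / nbins) * nt / 2
  phi <- matrix(stats::runif(nbins * m, 0, 2 * pi), nbins, m)
  amp * exp(1i * phi)
}

# Real series (nt x m) from one-sided in-band spectra via inverse FFT
series_from_spectra <- function(spec_mat, bins, nt) {
  m <- ncol(spec_mat)
  F <- matrix(0 + 0i, nt, m)
  F[1L + bins, ] <- spec_mat
  F[nt + 1L - bins, ] <- Conj(spec_mat)
  Re(stats::mvfft(F, inverse = TRUE)) / nt
}

sphere_mask_mm <- function(grid, center, radius) {
  xyz <- voxel_centers_mm(grid)
  d2 <- (xyz[, 1] - center[1])^2 + (xyz[, 2] - center[2])^2 +
    (xyz[, 3] - center[3])^2
  array(d2 <= radius^2, dim = grid$shape)
}

#' Generate a synthetic cohort
#'
#' Draws subject factors, phenotype and gray-matter maps eagerly; BOLD
#' volumes are reproduced on demand by [subject_bold()] from stored
#' per-subject seeds, so large cohorts never hold all series in memory.
#' The same `(spec, seed)` always yields an identical cohort.
#'
#' @param spec a `synthetic_spec`.
#' @param seed integer RNG seed.
#' @return a `synthetic_cohort`: grid, ROI list, tissue masks, phenotype
#'   data.frame (subject_id, center, sex, age, tcv, gmv), planted factors,
#'   gray-matter matrix, per-subject seeds, and the spec.
#' @export
generate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  grid0 <- grid_from_spacing(spec$shape, spec$voxel_mm)
  brain <- sphere_mask_mm(grid0, c(0, 0, 0), spec$brain_radius_mm)
  grid <- grid_from_spacing(spec$shape, spec$voxel_mm, brain_mask = brain)
  rois <- default_seed_rois(scale = spec$roi_scale,
                            radius_mm = spec$roi_radius_mm)
  roi_masks <- lapply(rois, sphere_roi_mask, grid = grid)
  wm_mask <- sphere_mask_mm(grid, spec$wm_center, spec$wm_radius) & brain
  csf_mask <- sphere_mask_mm(grid, spec$csf_center, spec$csf_radius) & brain
  region_union <- Reduce(`|`, roi_masks)
  if (any(region_union & (wm_mask | csf_mask))) {
    stop("tissue compartments overlap seed regions; adjust the spec")
  }
  n <- spec$n_subjects
  # phenotype
  center <- factor(rep_len(paste0("c", seq_len(spec$n_centers)), n))
  sex <- factor(sample(rep_len(c("F", "M"), n)))
  age <- stats::runif(n, spec$age_range[1], spec$age_range[2])
  # planted across-subject factors
  # explicit 2x2 Cholesky factor: valid for |corr| = 1 (degenerate) too
  corr_pair <- function(rho) {
    z <- matrix(stats::rnorm(2 * n), n, 2)
    cbind(z[, 1], rho * z[, 1] + sqrt(max(0, 1 - rho^2)) * z[, 2])
  }
  hl <- corr_pair(spec$amp_corr)
  gm_f <- corr_pair(spec$gm_corr)
  wm_amp <- 1 + spec$compartment_amp_sd * stats::rnorm(n)
  csf_amp <- 1 + spec$compartment_amp_sd * stats::rnorm(n)
  tcv_scale <- 1 + spec$tcv_sd * stats::rnorm(n)
  nuis <- spec$center_effect * (as.integer(center) - 1) +
    spec$sex_effect * (sex == "M") +
    spec$age_effect_per_decade * (age - mean(age)) / 10
  sets <- attr(rois, "sets")
  sysf <- ifelse(sets == "SN", 2L, 1L) # column of hl per region
  # region amplitudes, n x 9
  amp_noise <- matrix(stats::rnorm(n * length(rois)), n, length(rois))
  region_amp <- spec$amp_base *
    (1 + spec$amp_loading * hl[, sysf, drop = FALSE] + nuis +
       spec$amp_noise_sd * amp_noise)
  region_amp <- pmax(region_amp, 0.05)
  colnames(region_amp) <- names(rois)
  # gray-matter maps (subjects x voxels), eagerly
  nv <- n_voxels(grid)
  brain_idx <- which(brain)
  gm <- matrix(0, n, nv)
  bg_gm_idx <- which(brain & !region_union & !wm_mask & !csf_mask)
  for (s in seq_len(n)) {
    row <- numeric(nv)
    row[bg_gm_idx] <- spec$gm_background *
      (1 + spec$gm_noise_sd * stats::rnorm(length(bg_gm_idx)))
    for (g in seq_along(rois)) {
      idx <- which(roi_masks[[g]])
      row[idx] <- spec$gm_base *
        (1 + spec$gm_loading * gm_f[s, sysf[g]] +
           spec$gm_noise_sd * stats::rnorm(length(idx)))
    }
    gm[s, ] <- tcv_scale[s] * row
  }
  gmv <- rowSums(gm[, brain_idx, drop = FALSE])
  tcv <- tcv_scale * (sum(brain) * spec$voxel_mm^3)
  phenotype <- data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    center = center, sex = sex, age = age, tcv = tcv, gmv = gmv,
    stringsAsFactors = FALSE
  )
  subject_seeds <- sample.int(.Machine$integer.max - 1L, n)
  structure(
    list(spec = spec, seed = seed, grid = grid, rois = rois,
         roi_masks = roi_masks, wm_mask = wm_mask, csf_mask = csf_mask,
         phenotype = phenotype,
         factors = list(amplitude = hl, gm = gm_f, wm_amp = wm_amp,
                        csf_amp = csf_amp, tcv_scale = tcv_scale,
                        region_amp = region_amp),
         gm_matrix = gm, subject_seeds = subject_seeds),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d subjects on ", nrow(x$phenotype)))
  print(x$grid)
  invisible(x)
}

#' Reconstruct one subject's BOLD series
#'
#' Deterministic given the cohort (same subject index always yields the same
#' series). Non-brain voxels are zero.
#'
#' @param cohort a `synthetic_cohort`.
#' @param s subject index.
#' @return a `bold4d`.
#' @export
subject_bold <- function(cohort, s) {
  spec <- cohort$spec
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cohort$subject_seeds[s])
  nt <- spec$n_timepoints
  bins <- inband_bins(nt, spec$tr_seconds, spec$band_hz)
  K <- length(bins)
  grid <- cohort$grid
  brain_idx <- which(grid$brain_mask)
  nb <- length(brain_idx)
  # latent module spectra: DMN, TPN (anti-correlated), SN, WM, CSF
  U <- random_band_spectra(K, 4L, nt) # dmn, raw tpn, sn extra... columns
  c_t <- spec$dmn_tpn_temporal_corr
  U_dmn <- U[, 1]
  U_tpn <- c_t * U[, 1] + sqrt(1 - c_t^2) * U[, 2]
  U_sn <- U[, 3]
  U_wm <- U[, 4]
  U_csf <- random_band_spectra(K, 1L, nt)[, 1]
  # voxel-specific band-limited noise spectra for all brain voxels
  W <- random_band_spectra(K, nb, nt)
  # assemble per-voxel spectra
  amp_vox <- rep(spec$background_amp, nb)
  shared <- matrix(0 + 0i, K, nb)
  pos_of <- integer(n_voxels(grid)); pos_of[brain_idx] <- seq_len(nb)
  sets <- attr(cohort$rois, "sets")
  mod_spec <- list(DMN = U_dmn, TPN = U_tpn, SN = U_sn)
  rho <- spec$rho_time
  for (g in seq_along(cohort$rois)) {
    p <- pos_of[which(cohort$roi_masks[[g]])]
    a <- cohort$factors$region_amp[s, g]
    amp_vox[p] <- a
    shared[, p] <- sqrt(rho) * mod_spec[[sets[g]]]
  }
  for (comp in c("wm", "csf")) {
    mask <- if (comp == "wm") cohort$wm_mask else cohort$csf_mask
    p <- pos_of[which(mask)]
    a <- if (comp == "wm") cohort$factors$wm_amp[s] else cohort$factors$csf_amp[s]
    amp_vox[p] <- a
    shared[, p] <- sqrt(rho) * (if (comp == "wm") U_wm else U_csf)
  }
  w_share <- ifelse(abs(colSums(Mod(shared))) > 0, sqrt(1 - rho), 1)
  spectra <- sweep(shared + sweep(W, 2L, w_share, `*`), 2L, amp_vox, `*`)
  signal <- series_from_spectra(spectra, bins, nt)
  noise <- matrix(stats::rnorm(nt * nb, sd = spec$bold_noise_sd), nt, nb)
  data <- matrix(0, nt, n_voxels(grid))
  data[, brain_idx] <- signal + noise
  bold4d(data, grid, spec$tr_seconds)
}

#' One subject's gray-matter volume map
#' @param cohort a `synthetic_cohort`.
#' @param s subject index.
#' @return 3D numeric array.
#' @export
subject_gm <- function(cohort, s) {
  array(cohort$gm_matrix[s, ], dim = cohort$grid$shape)
}

#' Planted two-system ground-truth masks
#'
#' @param cohort a `synthetic_cohort`.
#' @return list with `high_mask` (union of DMN and TPN region voxels) and
#'   `low_mask` (union of sensory region voxels); always disjoint.
#' @export
ground_truth_masks <- function(cohort) {
  sets <- attr(cohort$rois, "sets")
  high <- Reduce(`|`, cohort$roi_masks[sets %in% c("DMN", "TPN")])
  low_masks <- cohort$roi_masks[sets == "SN"]
  low <- if (length(low_masks)) Reduce(`|`, low_masks) else
    array(FALSE, dim = cohort$grid$shape)
  list(high_mask = high, low_mask = low)
}

#' Write a synthetic cohort as an on-disk study
#'
#' Produces the directory layout the pipeline consumes: per-subject 4D BOLD
#' and 3D GM NIfTI volumes, brain/WM/CSF masks, a phenotype TSV, a seed-ROI
#' YAML and a ground-truth JSON.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "bold"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "gm"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  grid <- cohort$grid
  write_volume(grid$brain_mask * 1, grid, file.path(dir, "masks", "brain.nii.gz"))
  write_volume(cohort$wm_mask * 1, grid, file.path(dir, "masks", "wm.nii.gz"))
  write_volume(cohort$csf_mask * 1, grid, file.path(dir, "masks", "csf.nii.gz"))
  n <- nrow(cohort$phenotype)
  for (s in seq_len(n)) {
    id <- cohort$phenotype$subject_id[s]
    b <- subject_bold(cohort, s)
    write_bold(b, file.path(dir, "bold", paste0(id, "_bold.nii.gz")))
    write_volume(subject_gm(cohort, s), grid,
                 file.path(dir, "gm", paste0(id, "_gm.nii.gz")))
  }
  utils::write.table(cohort$phenotype, file.path(dir, "phenotype.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_roi_spec(cohort$rois, file.path(dir, "rois.yaml"))
  gt <- ground_truth_masks(cohort)
  jsonlite::write_json(
    list(high_voxels = which(gt$high_mask), low_voxels = which(gt$low_mask),
         seed = cohort$seed),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE)
  invisible(dir)
}
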