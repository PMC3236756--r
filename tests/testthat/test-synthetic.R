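# Small spec variants used across the generator tests
fast_spec <- function(...) {
  synthetic_spec(n_subjects = 6, n_timepoints = 64, ...)
}

test_that("the same spec and seed reproduce the cohort exactly", {
  co1 <- generate_cohort(fast_spec(), seed = 99)
  co2 <- generate_cohort(fast_spec(), seed = 99)
  expect_identical(co1$phenotype, co2$phenotype)
  expect_identical(co1$gm_matrix, co2$gm_matrix)
  expect_identical(co1$factors, co2$factors)
  b1 <- subject_bold(co1, 3); b2 <- subject_bold(co2, 3)
  expect_identical(b1$data, b2$data)
  # a different seed changes the data
  co3 <- generate_cohort(fast_spec(), seed = 100)
  expect_false(identical(co3$gm_matrix, co1$gm_matrix))
})

test_that("cohort generation does not disturb the caller's RNG stream", {
  set.seed(7); before <- rnorm(3)
  set.seed(7); invisible(generate_cohort(fast_spec(), seed = 1))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("ground-truth masks are the planted region unions and disjoint", {
  co <- generate_cohort(fast_spec(), seed = 5)
  gt <- ground_truth_masks(co)
  sets <- attr(co$rois, "sets")
  expect_equal(gt$high_mask,
               Reduce(`|`, co$roi_masks[sets %in% c("DMN", "TPN")]))
  expect_equal(gt$low_mask, Reduce(`|`, co$roi_masks[sets == "SN"]))
  expect_false(any(gt$high_mask & gt$low_mask))
  expect_false(any((gt$high_mask | gt$low_mask) & (co$wm_mask | co$csf_mask)))
})

test_that("a pure shared module signal makes within-region voxels correlate at 1", {
  spec <- fast_spec(rho_time = 1, bold_noise_sd = 0)
  co <- generate_cohort(spec, seed = 8)
  b <- subject_bold(co, 1)
  vox <- which(co$roi_masks$PCC)
  r <- cor(b$data[, vox[1]], b$data[, vox[2]])
  expect_equal(abs(r), 1, tolerance = 1e-8)
})

test_that("perfect amplitude anti-correlation survives the ALFF pipeline", {
  # fully degenerate amplitude model: no temporal or amplitude noise and no
  # cross-module temporal mixing (mixed spectra have random per-bin moduli,
  # which is amplitude noise in its own right)
  spec <- synthetic_spec(n_subjects = 20, n_timepoints = 150,
                         rho_time = 1, bold_noise_sd = 0, amp_noise_sd = 0,
                         compartment_amp_sd = 0, amp_corr = -1,
                         dmn_tpn_temporal_corr = 0,
                         center_effect = 0, sex_effect = 0,
                         age_effect_per_decade = 0)
  co <- generate_cohort(spec, seed = 9)
  gt <- ground_truth_masks(co)
  high <- low <- numeric(20)
  # detrending is off: removing a fitted trend from pure low-k sinusoids
  # perturbs the planted bins by a few percent per subject, which is noise
  # this degenerate-recovery check deliberately excludes
  for (s in 1:20) {
    a <- alff_pipeline(subject_bold(co, s), fwhm_mm = 0, detrend = FALSE)
    high[s] <- mean(a$values[gt$high_mask])
    low[s] <- mean(a$values[gt$low_mask])
  }
  expect_equal(cor(high, low), -1, tolerance = 0.01)
})

test_that("region mean ALFF recovers the planted loading at zero noise", {
  spec <- synthetic_spec(n_subjects = 24, n_timepoints = 150,
                         rho_time = 1, bold_noise_sd = 0, amp_noise_sd = 0,
                         compartment_amp_sd = 0,
                         center_effect = 0, sex_effect = 0,
                         age_effect_per_decade = 0)
  co <- generate_cohort(spec, seed = 10)
  nbins <- length(alffcn:::inband_bins(150, 2, c(0.01, 0.08)))
  pcc_alff <- vapply(1:24, function(s) {
    a <- alff_pipeline(subject_bold(co, s), fwhm_mm = 0, standardize = FALSE)
    mean(a$values[co$roi_masks$PCC])
  }, 0)
  h <- co$factors$amplitude[, 1]
  slope <- coef(lm(pcc_alff ~ h))[2]
  # a region of amplitude a and a single shared module signal has
  # ALFF = a * sqrt(2 / n_bins), so the slope in h is loading * sqrt(2/K)
  expected <- spec$amp_base * spec$amp_loading * sqrt(2 / nbins)
  expect_lt(abs(slope - expected) / expected, 0.1)
})

test_that("a planted centre offset is removed by covariate regression", {
  spec <- synthetic_spec(n_subjects = 60, n_timepoints = 96,
                         amp_loading = 0, center_effect = 0.3,
                         sex_effect = 0, age_effect_per_decade = 0)
  co <- generate_cohort(spec, seed = 11)
  n <- 60
  alff_mat <- matrix(0, n, prod(co$grid$shape))
  for (s in 1:n) {
    alff_mat[s, ] <- as.vector(alff_pipeline(subject_bold(co, s),
                                             fwhm_mm = 0)$values)
  }
  cm <- cohort_matrix(alff_mat, co$grid)
  seedv <- rowMeans(alff_mat[, as.vector(co$roi_masks$PCC)])
  partner <- as.vector(co$roi_masks$VC)
  raw <- fwe_threshold(crosssubject_covariance_map(cm, seedv))
  adj <- fwe_threshold(crosssubject_covariance_map(
    cm, seedv, covariates = covariate_matrix(co$phenotype, "center")))
  # the shared site effect inflates the raw fit; the adjusted one is null
  expect_gt(max(abs(raw$source$t[partner])), max(abs(adj$source$t[partner])))
  expect_lt(max(abs(adj$source$t[partner])), adj$t_crit)
})

test_that("written studies contain everything the pipeline needs", {
  co <- generate_cohort(fast_spec(), seed = 12)
  dir <- file.path(tempdir(), "study_fixture")
  unlink(dir, recursive = TRUE)
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "phenotype.tsv")))
  expect_true(file.exists(file.path(dir, "rois.yaml")))
  expect_true(file.exists(file.path(dir, "masks", "brain.nii.gz")))
  expect_length(list.files(file.path(dir, "bold"), pattern = "nii.gz$"), 6L)
  # round-trip: BOLD read back equals the generated series
  b <- read_bold(file.path(dir, "bold", "S003_bold.nii.gz"))
  expect_equal(b$tr_seconds, 2)
  orig <- subject_bold(co, 3)
  expect_equal(b$data, orig$data, tolerance = 1e-6)
  expect_true(same_grid(b$grid, co$grid))
  phen <- read_phenotype(file.path(dir, "phenotype.tsv"))
  expect_equal(phen$subject_id, co$phenotype$subject_id)
  unlink(dir, recursive = TRUE)
})

test_that("planted anti-correlated temporal modules drive the ICN dichotomy", {
  spec <- synthetic_spec(n_subjects = 10, n_timepoints = 150)
  co <- generate_cohort(spec, seed = 13)
  n <- 10
  sets <- attr(co$rois, "sets")
  dmn_idx <- which(sets == "DMN"); tpn_idx <- which(sets == "TPN")
  dmn_maps <- vector("list", n); tpn_maps <- vector("list", n)
  for (s in 1:n) {
    b <- spatial_smooth(subject_bold(co, s), 2.8, mask = co$grid$brain_mask)
    b <- bandpass_filter(b, 0.01, 0.08)
    nuis <- cbind(wm = roi_mean(b, co$wm_mask), csf = roi_mean(b, co$csf_mask),
                  global = roi_mean(b, co$grid$brain_mask))
    zz <- subject_icn_maps(b, co$roi_masks, nuis)
    dmn_maps[[s]] <- lapply(dmn_idx, function(g) zz[[g]])
    tpn_maps[[s]] <- lapply(tpn_idx, function(g) zz[[g]])
  }
  dich <- ts_icn_dichotomy(dmn_maps, tpn_maps, co$grid, alpha = 0.05)
  tpn_mask <- Reduce(`|`, co$roi_masks[tpn_idx])
  dmn_mask <- Reduce(`|`, co$roi_masks[dmn_idx])
  expect_gte(jaccard(dich$thresholded$pos_mask, tpn_mask), 0.8)
  expect_gte(jaccard(dich$thresholded$neg_mask, dmn_mask), 0.8)
})
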