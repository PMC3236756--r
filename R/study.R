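#' Study configuration
#'
#' Collects every parameter of the end-to-end pipeline with the conventional
#' defaults: 0.01-0.08 Hz pass band, 8 mm FWHM smoothing, FWE alpha 0.05,
#' 2-of-3 intra-set and 8-of-9 inter-set conjunction rules with the sensory
#' set sign-flipped, average-linkage clustering of 1 - r dissimilarities cut
#' at 0.4, and global-signal regression for the within-subject estimator.
#'
#' The study directory is expected to contain `bold/<id>_bold.nii.gz`,
#' `gm/<id>_gm.nii.gz`, `masks/{brain,wm,csf}.nii.gz`, `phenotype.tsv` (or
#' .csv) and `rois.yaml` — the layout written by [write_cohort()].
#'
#' @param study_dir input study directory.
#' @param out_dir output directory.
#' @param band_hz temporal pass band (Hz).
#' @param fwhm_mm spatial smoothing kernel FWHM (mm); 0 disables.
#' @param alpha_fwe family-wise error level.
#' @param k_intra,k_inter conjunction counting thresholds.
#' @param flip_set seed set sign-flipped in the inter-set conjunction.
#' @param dissimilarity_method,linkage,cut_height clustering parameters.
#' @param global_signal regress the global mean signal in the within-subject
#'   estimator.
#' @param detrend linear detrend before temporal filtering.
#' @param min_cluster_voxels minimum reported cluster extent.
#' @param estimators which network estimators to run.
#' @param seed RNG seed recorded in the manifest (the analysis itself is
#'   deterministic).
#' @return an object of class `study_config`.
#' @export
study_config <- function(study_dir, out_dir,
                         band_hz = c(0.01, 0.08), fwhm_mm = 8,
                         alpha_fwe = 0.05, k_intra = 2L, k_inter = 8L,
                         flip_set = "SN",
                         dissimilarity_method = "one_minus_r",
                         linkage = "average", cut_height = 0.4,
                         global_signal = TRUE, detrend = TRUE,
                         min_cluster_voxels = 5L,
                         estimators = c("ALFF-FCN", "TS-ICN", "VBM-SCN"),
                         seed = 1L) {
  stopifnot(length(band_hz) == 2, band_hz[1] < band_hz[2], fwhm_mm >= 0,
            alpha_fwe > 0, alpha_fwe < 1, cut_height >= 0)
  cfg <- as.list(environment())
  class(cfg) <- "study_config"
  cfg
}

#' Read a study configuration from YAML
#'
#' Keys mirror the arguments of [study_config()]; unknown keys are rejected.
#'
#' @param path YAML file.
#' @param ... overrides applied after reading.
#' @export
read_study_config <- function(path, ...) {
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(study_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  }
  do.call(study_config, vals)
}

study_paths <- function(cfg) {
  sd <- cfg$study_dir
  phen <- file.path(sd, "phenotype.tsv")
  if (!file.exists(phen)) phen <- file.path(sd, "phenotype.csv")
  list(
    bold_dir = file.path(sd, "bold"),
    gm_dir = file.path(sd, "gm"),
    brain_mask = file.path(sd, "masks", "brain.nii.gz"),
    wm_mask = file.path(sd, "masks", "wm.nii.gz"),
    csf_mask = file.path(sd, "masks", "csf.nii.gz"),
    phenotype = phen,
    rois = file.path(sd, "rois.yaml")
  )
}

#' Validate the inputs of a study
#'
#' Checks that every referenced file exists, grids agree, the phenotype is
#' complete (one row per BOLD volume), every ROI falls inside the brain
#' mask, and a repetition time is recoverable. Never mutates data.
#'
#' @param cfg a `study_config`.
#' @return character vector of human-readable failures (empty when clean).
#' @export
validate_inputs <- function(cfg) {
  p <- study_paths(cfg)
  fail <- character(0)
  for (f in c(p$brain_mask, p$wm_mask, p$csf_mask, p$phenotype, p$rois)) {
    if (!file.exists(f)) fail <- c(fail, sprintf("missing file: %s", f))
  }
  if (length(fail)) return(fail)
  brain <- read_volume(p$brain_mask)
  grid <- volume_grid(brain$grid$shape, brain$grid$affine,
                      brain$values > 0.5)
  for (nm in c("wm_mask", "csf_mask")) {
    v <- read_volume(p[[nm]])
    if (!same_grid(grid, v$grid)) {
      fail <- c(fail, sprintf("grid mismatch: %s vs %s", p[[nm]], p$brain_mask))
    }
  }
  phen <- tryCatch(read_phenotype(p$phenotype), error = function(e) {
    fail <<- c(fail, sprintf("phenotype: %s", conditionMessage(e)))
    NULL
  })
  rois <- tryCatch(read_roi_spec(p$rois), error = function(e) {
    fail <<- c(fail, sprintf("roi spec: %s", conditionMessage(e)))
    NULL
  })
  if (!is.null(rois)) {
    for (r in rois) {
      ok <- tryCatch({sphere_roi_mask(r, grid); TRUE},
                     error = function(e) FALSE)
      if (!ok) fail <- c(fail, sprintf("ROI '%s' is outside the brain mask", r$name))
    }
  }
  if (!is.null(phen)) {
    for (id in phen$subject_id) {
      bf <- file.path(p$bold_dir, paste0(id, "_bold.nii.gz"))
      gf <- file.path(p$gm_dir, paste0(id, "_gm.nii.gz"))
      if (!file.exists(bf)) fail <- c(fail, sprintf("subject %s: missing BOLD %s", id, bf))
      if (!file.exists(gf)) fail <- c(fail, sprintf("subject %s: missing GM %s", id, gf))
      if (file.exists(bf) && !file.exists(sidecar_path(bf))) {
        img_tr <- RNifti::pixdim(RNifti::readNifti(bf, internal = TRUE))
        if (length(img_tr) < 4 || img_tr[4] <= 0) {
          fail <- c(fail, sprintf("subject %s: no repetition time available", id))
        }
      }
    }
  }
  fail
}

#' Run the full network study
#'
#' End-to-end pipeline: per-subject ALFF maps (smooth, filter, ALFF,
#' standardize), the three network estimators for every seed, FWE
#' thresholding, cluster tables, hierarchical clustering of each estimator's
#' nine maps, intra-set conjunctions, the inter-set conjunction of the
#' across-subject ALFF networks (sensory set sign-flipped), the
#' within-subject network dichotomy, and the two-system dichotomy
#' statistics. All results are written under `cfg$out_dir` together with a
#' machine-readable manifest; the run is deterministic given inputs and
#' configuration.
#'
#' @param cfg a `study_config`.
#' @return a `study_report` (invisibly the same content as the manifest):
#'   list of stat maps, thresholded maps, cluster tables, clusterings,
#'   conjunction maps, the dichotomy result, and output paths.
#' @export
run_study <- function(cfg) {
  fails <- validate_inputs(cfg)
  if (length(fails)) {
    stop("invalid study inputs:\n  ", paste(fails, collapse = "\n  "))
  }
  p <- study_paths(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  brain <- read_volume(p$brain_mask)
  grid <- volume_grid(brain$grid$shape, brain$grid$affine, brain$values > 0.5)
  wm_mask <- read_volume(p$wm_mask)$values > 0.5
  csf_mask <- read_volume(p$csf_mask)$values > 0.5
  phen <- read_phenotype(p$phenotype)
  rois <- read_roi_spec(p$rois)
  roi_sets <- split_roi_sets(rois)
  roi_masks <- lapply(rois, sphere_roi_mask, grid = grid)
  n <- nrow(phen)
  nv <- n_voxels(grid)

  do_fcn <- "ALFF-FCN" %in% cfg$estimators
  do_icn <- "TS-ICN" %in% cfg$estimators
  do_scn <- "VBM-SCN" %in% cfg$estimators

  alff_mat <- matrix(0, n, nv)
  wm_alff <- csf_alff <- numeric(n)
  icn_z <- if (do_icn) {
    lapply(rois, function(r) matrix(0, n, nv))
  }
  for (s in seq_len(n)) {
    id <- phen$subject_id[s]
    bold <- read_bold(file.path(p$bold_dir, paste0(id, "_bold.nii.gz")),
                      brain_mask = grid$brain_mask)
    if (!same_grid(bold$grid, grid)) {
      stop(sprintf("grid mismatch for subject %s BOLD", id))
    }
    if (cfg$fwhm_mm > 0) {
      bold <- spatial_smooth(bold, cfg$fwhm_mm, mask = grid$brain_mask)
    }
    bold <- bandpass_filter(bold, cfg$band_hz[1], cfg$band_hz[2],
                            detrend = cfg$detrend)
    alff <- standardize_alff(compute_alff_map(bold, cfg$band_hz))
    alff_mat[s, ] <- as.vector(alff$values)
    wm_alff[s] <- roi_mean(alff$values, wm_mask)
    csf_alff[s] <- roi_mean(alff$values, csf_mask)
    if (do_icn) {
      nuis <- cbind(wm = roi_mean(bold, wm_mask),
                    csf = roi_mean(bold, csf_mask))
      if (cfg$global_signal) {
        nuis <- cbind(nuis, global = roi_mean(bold, grid$brain_mask))
      }
      zs <- subject_icn_maps(bold, roi_masks, nuis)
      for (r in names(rois)) icn_z[[r]][s, ] <- as.vector(zs[[r]])
    }
  }
  alff_cohort <- cohort_matrix(alff_mat, grid, phen$subject_id, "alff")

  gm_cohort <- NULL
  if (do_scn) {
    gm_mat <- matrix(0, n, nv)
    for (s in seq_len(n)) {
      v <- read_volume(file.path(p$gm_dir,
                                 paste0(phen$subject_id[s], "_gm.nii.gz")))
      if (!same_grid(v$grid, grid)) {
        stop(sprintf("grid mismatch for subject %s GM", phen$subject_id[s]))
      }
      gm_mat[s, ] <- as.vector(v$values)
    }
    gm_cohort <- cohort_matrix(gm_mat, grid, phen$subject_id, "gmv")
    if (is.null(phen$gmv)) {
      phen$gmv <- rowSums(gm_mat[, as.vector(grid$brain_mask), drop = FALSE])
    }
    if (is.null(phen$tcv)) phen$tcv <- phen$gmv
  }

  demo_cov <- covariate_matrix(phen, c("center", "sex", "age"))
  stat_maps <- list(); thr_maps <- list()
  for (r in names(rois)) {
    if (do_fcn) {
      seed_vals <- vapply(seq_len(n), function(s) {
        mean(alff_mat[s, as.vector(roi_masks[[r]])])
      }, 0)
      cov_fcn <- cbind(wm_alff = wm_alff, csf_alff = csf_alff, demo_cov)
      stat_maps[[paste0("ALFF-FCN.", r)]] <-
        crosssubject_covariance_map(alff_cohort, seed_vals, cov_fcn,
                                    estimator = "ALFF-FCN", seed_name = r)
    }
    if (do_icn) {
      stat_maps[[paste0("TS-ICN.", r)]] <-
        group_onesample_t(icn_z[[r]], grid, demo_cov,
                          estimator = "TS-ICN", seed_name = r)
    }
    if (do_scn) {
      gm_seed <- vapply(seq_len(n), function(s) {
        mean(gm_cohort$data[s, as.vector(roi_masks[[r]])])
      }, 0)
      cov_scn <- cbind(tcv = phen$tcv, gmv = phen$gmv, demo_cov)
      stat_maps[[paste0("VBM-SCN.", r)]] <-
        vbm_scn_map(gm_cohort, gm_seed, cov_scn, seed_name = r)
    }
  }
  for (nm in names(stat_maps)) {
    thr_maps[[nm]] <- fwe_threshold(stat_maps[[nm]], cfg$alpha_fwe)
  }

  map_dir <- file.path(cfg$out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  cluster_tables <- list()
  for (nm in names(thr_maps)) {
    write_thresholded_map(thr_maps[[nm]], file.path(map_dir, nm))
    tab <- cluster_table(thr_maps[[nm]], cfg$min_cluster_voxels)
    cluster_tables[[nm]] <- tab
    write_cluster_table(tab, file.path(map_dir, paste0(nm, "_clusters.tsv")))
  }

  # hierarchical clustering of each estimator's nine maps
  clusterings <- list(); distances <- list()
  for (est in cfg$estimators) {
    maps <- stat_maps[grep(paste0("^", est, "\\."), names(stat_maps))]
    names(maps) <- sub("^[^.]+\\.", "", names(maps))
    if (length(maps) < 2) next
    dm <- map_distance_matrix(maps, method = cfg$dissimilarity_method)
    distances[[est]] <- dm
    clusterings[[est]] <- hierarchical_cluster(dm, cfg$linkage,
                                               cfg$cut_height)
    utils::write.table(dm$d, file.path(cfg$out_dir,
                                       paste0(est, "_distance.tsv")),
                       sep = "\t", quote = FALSE)
    jsonlite::write_json(
      list(merge = clusterings[[est]]$tree$merge,
           height = clusterings[[est]]$tree$height,
           labels = clusterings[[est]]$tree$labels,
           cut_height = cfg$cut_height,
           partition = as.list(clusterings[[est]]$partition)),
      file.path(cfg$out_dir, paste0(est, "_dendrogram.json")),
      auto_unbox = TRUE, digits = NA)
  }

  # conjunctions (across-subject ALFF networks)
  conjunctions <- list()
  if (do_fcn) {
    set_names <- names(roi_sets)
    fcn_sets <- lapply(roi_sets, function(set) {
      lapply(names(set), function(r) thr_maps[[paste0("ALFF-FCN.", r)]])
    })
    for (sn in set_names) {
      conjunctions[[paste0("FCN_intra_", sn)]] <-
        conjunction_intra_set(fcn_sets[[sn]], k = cfg$k_intra)
    }
    if (cfg$flip_set %in% set_names && length(set_names) > 1) {
      conjunctions[["FCN_inter"]] <-
        conjunction_inter_set(fcn_sets, flip_set = cfg$flip_set,
                              k = cfg$k_inter)
    }
  }
  if (do_icn && all(c("DMN", "TPN") %in% names(roi_sets))) {
    set_of <- attr(rois, "sets")
    avg_set_maps <- function(set) {
      idx <- which(set_of == set)
      lapply(seq_len(n), function(s) {
        array(colMeans(do.call(rbind, lapply(idx, function(g) {
          icn_z[[g]][s, ]
        }))), dim = grid$shape)
      })
    }
    dich <- ts_icn_dichotomy(avg_set_maps("DMN"), avg_set_maps("TPN"),
                             grid, demo_cov, cfg$alpha_fwe)
    conjunctions[["ICN_dichotomy"]] <- dich$thresholded
    write_thresholded_map(dich$thresholded,
                          file.path(map_dir, "TS-ICN.dichotomy"))
    for (sn in names(roi_sets)) {
      icn_thr <- lapply(names(roi_sets[[sn]]), function(r) {
        thr_maps[[paste0("TS-ICN.", r)]]
      })
      conjunctions[[paste0("ICN_intra_", sn)]] <-
        conjunction_intra_set(icn_thr, k = cfg$k_intra)
    }
  }
  for (nm in names(conjunctions)) {
    cj <- conjunctions[[nm]]
    if (inherits(cj, "conjunction_map")) {
      write_volume(cj$pos_mask, grid,
                   file.path(cfg$out_dir, paste0(nm, "_pos.nii.gz")))
      write_volume(cj$neg_mask, grid,
                   file.path(cfg$out_dir, paste0(nm, "_neg.nii.gz")))
    }
  }

  dichotomy <- NULL
  if (do_fcn && !is.null(conjunctions[["FCN_inter"]])) {
    cj <- conjunctions[["FCN_inter"]]
    if (any(cj$pos_mask) && any(cj$neg_mask)) {
      dichotomy <- dichotomy_statistics(alff_cohort, cj$pos_mask, cj$neg_mask)
      jsonlite::write_json(
        list(r = dichotomy$r, r_pvalue = dichotomy$r_pvalue,
             t = dichotomy$t_twosample, t_pvalue = dichotomy$t_pvalue,
             high_mean = dichotomy$high_mean, high_sd = dichotomy$high_sd,
             low_mean = dichotomy$low_mean, low_sd = dichotomy$low_sd,
             n = n),
        file.path(cfg$out_dir, "dichotomy.json"), auto_unbox = TRUE,
        digits = NA)
    }
  }

  out_files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  out_files <- setdiff(out_files, file.path(cfg$out_dir, "manifest.json"))
  checksums <- tools::md5sum(sort(out_files))
  names(checksums) <- substring(names(checksums), nchar(cfg$out_dir) + 2L)
  manifest <- list(
    parameters = unclass(cfg)[setdiff(names(cfg), c("study_dir", "out_dir"))],
    n_subjects = n,
    estimators = cfg$estimators,
    stat_maps = names(stat_maps),
    conjunctions = names(conjunctions),
    checksums = as.list(checksums)
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report <- structure(
    list(grid = grid, stat_maps = stat_maps, thresholded = thr_maps,
         cluster_tables = cluster_tables, distances = distances,
         clusterings = clusterings, conjunctions = conjunctions,
         dichotomy = dichotomy, alff_cohort = alff_cohort,
         manifest = manifest, out_dir = cfg$out_dir),
    class = "study_report"
  )
  invisible(report)
}

#' @export
print.study_report <- function(x, ...) {
  cat(sprintf("study_report: %d stat maps, %d conjunction maps -> %s\n",
              length(x$stat_maps), length(x$conjunctions), x$out_dir))
  if (!is.null(x$dichotomy)) print(x$dichotomy)
  invisible(x)
}
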