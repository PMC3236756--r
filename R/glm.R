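# Vectorized least squares over many response columns.
# Returns the t statistic of column `coef_index` of X for every column of Y,
# plus df and a logical vector flagging zero-residual-variance responses
# (their t is capped at +/- t_cap instead of propagating NaN/Inf).
fit_coef_t <- function(Y, X, coef_index, t_cap = 1e8) {
  n <- nrow(X); p <- ncol(X)
  df <- n - p
  if (df <= 0) stop(sprintf("insufficient degrees of freedom: n = %d, model columns = %d", n, p))
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):p]]
    stop(sprintf("design matrix is rank deficient (collinear columns: %s)",
                 paste(bad, collapse = ", ")))
  }
  coef <- qr.coef(qrX, Y)
  res <- Y - X %*% coef
  s2 <- colSums(res^2) / df
  R <- qr.R(qrX)
  xtx_inv <- matrix(NA_real_, p, p)
  xtx_inv[qrX$pivot, qrX$pivot] <- chol2inv(R)
  se <- sqrt(pmax(s2, 0) * xtx_inv[coef_index, coef_index])
  tt <- coef[coef_index, ] / se
  degenerate <- s2 <= .Machine$double.eps * max(1, mean(colSums(Y^2)) / n)
  if (any(degenerate)) {
    tt[degenerate] <- sign(coef[coef_index, degenerate]) * t_cap
    tt[degenerate & coef[coef_index, ] == 0] <- 0
  }
  tt[!is.finite(tt)] <- 0
  list(t = tt, df = df, degenerate = degenerate, coef = coef[coef_index, ])
}

#' Build a centred covariate design from a phenotype table
#'
#' Categorical variables (factors/characters) become treatment-coded dummy
#' columns; every column is then mean-centred, so an intercept elsewhere in
#' the model is interpretable as the covariate-adjusted mean.
#'
#' @param phenotype data.frame of covariates.
#' @param vars character vector of column names to use; default all columns.
#' @return numeric matrix with n rows and zero column means, or a 0-column
#'   matrix when `vars` is empty.
#' @export
covariate_matrix <- function(phenotype, vars = colnames(phenotype)) {
  if (length(vars) == 0L) {
    return(matrix(numeric(0), nrow = nrow(phenotype), ncol = 0))
  }
  missing_vars <- setdiff(vars, colnames(phenotype))
  if (length(missing_vars)) {
    stop("phenotype is missing covariate columns: ",
         paste(missing_vars, collapse = ", "))
  }
  d <- phenotype[, vars, drop = FALSE]
  if (anyNA(d)) stop("missing values among covariates")
  for (v in vars) if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
  X <- stats::model.matrix(~ ., data = d)[, -1, drop = FALSE]
  sweep(X, 2L, colMeans(X), `-`)
}

#' A voxel-wise t statistic map
#'
#' @param t_values 3D numeric array of t statistics.
#' @param grid the `volume_grid`.
#' @param df residual degrees of freedom.
#' @param estimator one of "TS-ICN", "ALFF-FCN", "VBM-SCN" (free-form allowed).
#' @param seed_name name of the seed region the map belongs to.
#' @param degenerate optional logical array flagging zero-variance voxels.
#' @export
stat_map <- function(t_values, grid, df, estimator = NA_character_,
                     seed_name = NA_character_, degenerate = NULL) {
  stopifnot(identical(dim(t_values), grid$shape), df > 0)
  structure(
    list(t = t_values, grid = grid, df = as.integer(df),
         estimator = estimator, seed_name = seed_name,
         degenerate = degenerate),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  tm <- x$t[x$grid$brain_mask]
  cat(sprintf("stat_map [%s, seed %s]: df = %d, t range %.3g .. %.3g\n",
              x$estimator, x$seed_name, x$df, min(tm), max(tm)))
  invisible(x)
}

#' Subject-level seed connectivity map (Fisher z)
#'
#' Residualizes the seed time series and every voxel time series against the
#' nuisance matrix (an intercept is always included), computes the Pearson
#' correlation of the residuals per voxel, and returns the Fisher
#' z = atanh(r) map with |r| clipped to 1 - 1e-7. Voxels whose residual
#' series is constant get z = 0 and are flagged.
#'
#' @param bold a `bold4d`.
#' @param seed_mask logical array on the same grid.
#' @param nuisance T x k numeric matrix (may have 0 columns); e.g. motion
#'   parameters, WM/CSF mean signals, the global signal.
#' @return 3D array of Fisher z values, attributes `flagged` (logical array)
#'   and `df_time` (T - k - 1).
#' @export
subject_icn_map <- function(bold, seed_mask, nuisance = NULL) {
  subject_icn_maps(bold, list(seed_mask), nuisance)[[1]]
}

#' Subject-level connectivity maps for several seeds at once
#'
#' Same contract as [subject_icn_map()], but the voxel series are
#' residualized against the nuisance matrix once and correlated with every
#' seed's residual series (residualizing the seed mean and averaging the
#' residualized voxel series commute, so the result is identical).
#'
#' @inheritParams subject_icn_map
#' @param seed_masks list of logical arrays.
#' @return list of Fisher-z arrays, one per seed.
#' @export
subject_icn_maps <- function(bold, seed_masks, nuisance = NULL) {
  stopifnot(inherits(bold, "bold4d"))
  nt <- nrow(bold$data)
  if (is.null(nuisance)) nuisance <- matrix(numeric(0), nt, 0)
  nuisance <- as.matrix(nuisance)
  stopifnot(nrow(nuisance) == nt)
  if (nt <= ncol(nuisance) + 3L) stop("too few time points for the nuisance model")
  X <- cbind(intercept = 1, nuisance)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop(sprintf("nuisance matrix is rank deficient (collinear columns: %s)",
                 paste(bad, collapse = ", ")))
  }
  vox_res <- qr.resid(qrX, bold$data)
  vox_ss <- colSums(vox_res^2)
  flagged <- vox_ss <= .Machine$double.eps * nt
  lapply(seed_masks, function(seed_mask) {
    if (!any(seed_mask)) stop("empty seed mask")
    seed_res <- rowMeans(vox_res[, as.vector(seed_mask), drop = FALSE])
    seed_ss <- sum(seed_res^2)
    if (seed_ss <= 0) stop("seed residual series is constant")
    denom <- sqrt(seed_ss * vox_ss)
    r <- as.vector(crossprod(seed_res, vox_res)) / ifelse(flagged, 1, denom)
    r[flagged] <- 0
    r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
    z <- array(atanh(r), dim = bold$grid$shape)
    attr(z, "flagged") <- array(flagged, dim = bold$grid$shape)
    attr(z, "df_time") <- nt - ncol(X)
    z
  })
}

#' Group-level one-sample t map with covariates
#'
#' Fits, per voxel, `value ~ 1 + centred covariates` across subjects and
#' returns the t statistic of the intercept (the covariate-adjusted group
#' mean), the random-effects group inference used for within-subject seed
#' maps.
#'
#' @param maps list of 3D arrays (one per subject) or a subjects x voxels
#'   matrix.
#' @param grid the `volume_grid`.
#' @param covariates subjects x c numeric matrix (centred internally), or
#'   `NULL`.
#' @param estimator,seed_name metadata carried into the result.
#' @return a `stat_map` with df = n - 1 - c.
#' @export
group_onesample_t <- function(maps, grid, covariates = NULL,
                              estimator = "TS-ICN", seed_name = NA_character_) {
  Y <- if (is.matrix(maps)) maps else
    do.call(rbind, lapply(maps, function(m) as.vector(m)))
  n <- nrow(Y)
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  covariates <- as.matrix(covariates)
  if (ncol(covariates) > 0) {
    covariates <- sweep(covariates, 2L, colMeans(covariates), `-`)
  }
  X <- cbind(intercept = 1, covariates)
  fit <- fit_coef_t(Y, X, coef_index = 1L)
  stat_map(array(fit$t, dim = grid$shape), grid, fit$df,
           estimator = estimator, seed_name = seed_name,
           degenerate = array(fit$degenerate, dim = grid$shape))
}

#' A cohort measurement matrix (subjects x voxels)
#'
#' One scalar measure per subject and voxel — standardized ALFF or gray
#' matter volume — with rows aligned to the phenotype table.
#'
#' @param data subjects x voxels numeric matrix (voxels in array order).
#' @param grid the `volume_grid`.
#' @param subject_ids character vector, one per row.
#' @param measure free-form label ("alff", "gmv").
#' @export
cohort_matrix <- function(data, grid, subject_ids = rownames(data),
                          measure = NA_character_) {
  data <- as.matrix(data)
  stopifnot(ncol(data) == n_voxels(grid))
  if (anyNA(data)) stop("cohort matrix contains missing values")
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(nrow(data)))
  stopifnot(length(subject_ids) == nrow(data))
  structure(list(data = data, grid = grid, subject_ids = subject_ids,
                 measure = measure),
            class = "cohort_matrix")
}

#' @export
print.cohort_matrix <- function(x, ...) {
  cat(sprintf("cohort_matrix [%s]: %d subjects x %d voxels\n",
              x$measure, nrow(x$data), ncol(x$data)))
  invisible(x)
}

#' Across-subject covariance network map
#'
#' Fits, per voxel v, `value_v ~ 1 + seed + covariates` across subjects and
#' returns the t statistic of the seed regressor — equivalently the partial
#' correlation t of (value_v, seed | covariates) with df = n - 2 - c. This is
#' the engine of both the ALFF functional covariance network (seed = mean
#' standardized ALFF in the seed region) and the structural covariance
#' network (seed = mean gray-matter volume).
#'
#' @param cohort a `cohort_matrix`.
#' @param seed_values numeric vector, one value per subject; must not be
#'   constant.
#' @param covariates subjects x c numeric matrix (centred internally) or NULL.
#' @param estimator,seed_name metadata for the result.
#' @return a `stat_map` with df = n - 2 - c.
#' @export
crosssubject_covariance_map <- function(cohort, seed_values, covariates = NULL,
                                        estimator = "ALFF-FCN",
                                        seed_name = NA_character_) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  n <- nrow(cohort$data)
  stopifnot(length(seed_values) == n)
  if (stats::sd(seed_values) == 0) stop("seed_values is constant across subjects")
  if (is.null(covariates)) covariates <- matrix(numeric(0), n, 0)
  covariates <- as.matrix(covariates)
  if (n <= ncol(covariates) + 3L) stop("too few subjects for the covariate model")
  if (ncol(covariates) > 0) {
    covariates <- sweep(covariates, 2L, colMeans(covariates), `-`)
  }
  X <- cbind(intercept = 1, seed = seed_values, covariates)
  fit <- fit_coef_t(cohort$data, X, coef_index = 2L)
  stat_map(array(fit$t, dim = cohort$grid$shape), cohort$grid, fit$df,
           estimator = estimator, seed_name = seed_name,
           degenerate = array(fit$degenerate, dim = cohort$grid$shape))
}

#' Structural covariance network map
#'
#' Same engine as [crosssubject_covariance_map()], with the seed regressor
#' being the subject-wise mean gray-matter volume in the seed region; the
#' conventional covariates are total cranial volume, whole gray-matter
#' volume, centre, sex and age.
#'
#' @inheritParams crosssubject_covariance_map
#' @param gm_cohort a `cohort_matrix` of gray-matter volume maps.
#' @param roi_gm_means subject-wise mean GM volume inside the seed ROI.
#' @export
vbm_scn_map <- function(gm_cohort, roi_gm_means, covariates = NULL,
                        seed_name = NA_character_) {
  crosssubject_covariance_map(gm_cohort, roi_gm_means, covariates,
                              estimator = "VBM-SCN", seed_name = seed_name)
}

#' Family-wise-error threshold of a t map (Bonferroni)
#'
#' Two-sided Bonferroni control over the in-mask voxels: the critical value
#' is the upper alpha / (2 V) quantile of Student's t with the map's degrees
#' of freedom, V the number of in-mask voxels.
#'
#' @param stat a `stat_map`.
#' @param alpha family-wise error level, default 0.05.
#' @param mask logical array; defaults to the grid brain mask.
#' @return a `thresholded_map`: the source map plus `alpha_fwe`, `t_crit`,
#'   and disjoint `pos_mask` / `neg_mask` logical arrays.
#' @export
fwe_threshold <- function(stat, alpha = 0.05, mask = NULL) {
  stopifnot(inherits(stat, "stat_map"), alpha > 0, alpha < 1)
  if (is.null(mask)) mask <- stat$grid$brain_mask
  V <- sum(mask)
  stopifnot(V >= 1)
  t_crit <- stats::qt(1 - alpha / (2 * V), df = stat$df)
  pos <- mask & (stat$t >= t_crit)
  neg <- mask & (stat$t <= -t_crit)
  structure(
    list(source = stat, grid = stat$grid, alpha_fwe = alpha, t_crit = t_crit,
         n_comparisons = V, pos_mask = pos, neg_mask = neg),
    class = "thresholded_map"
  )
}

#' @export
print.thresholded_map <- function(x, ...) {
  cat(sprintf(
    "thresholded_map [%s, seed %s]: FWE alpha %.3g over %d voxels, |t| >= %.3f; %d positive, %d negative voxels\n",
    x$source$estimator, x$source$seed_name, x$alpha_fwe, x$n_comparisons,
    x$t_crit, sum(x$pos_mask), sum(x$neg_mask)))
  invisible(x)
}

# 26-connectivity connected components of a logical 3D array.
# Returns an integer array of component labels (0 = background).
connected_components_26 <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, dim = d)
  idx_all <- which(mask)
  if (length(idx_all) == 0L) return(labels)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  in_mask <- mask
  lab <- 0L
  for (start in idx_all) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    queue <- start
    labels[start] <- lab
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cc <- arrayInd(cur, d)
      nb <- sweep(offs, 2L, as.integer(cc), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
        nb[, 2] >= 1 & nb[, 2] <= d[2] &
        nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- nb[, 1] + d[1] * (nb[, 2] - 1L) + d[1] * d[2] * (nb[, 3] - 1L)
      new <- lin[in_mask[lin] & labels[lin] == 0L]
      if (length(new)) {
        labels[new] <- lab
        queue <- c(queue, new)
      }
    }
  }
  labels
}

#' Cluster table of a thresholded map
#'
#' Connected components (26-connectivity) are found separately on the
#' positive and negative significance masks; components smaller than
#' `min_voxels` are dropped. Each row reports the component's peak |t| voxel
#' (MNI mm), the signed peak t, and the voxel count; rows are sorted by
#' voxel count, descending.
#'
#' @param thr a `thresholded_map`.
#' @param min_voxels minimum cluster extent, default 1.
#' @return data.frame with columns `label`, `x`, `y`, `z`, `peak_t`, `voxels`.
#' @export
cluster_table <- function(thr, min_voxels = 1L) {
  stopifnot(inherits(thr, "thresholded_map"))
  rows <- list()
  for (sign_lab in c("pos", "neg")) {
    mask <- if (sign_lab == "pos") thr$pos_mask else thr$neg_mask
    labels <- connected_components_26(mask)
    if (max(labels) == 0L) next
    for (l in seq_len(max(labels))) {
      vox <- which(labels == l)
      if (length(vox) < min_voxels) next
      tv <- thr$source$t[vox]
      peak <- vox[which.max(abs(tv))]
      ijk <- arrayInd(peak, dim(mask)) - 1L
      mm <- voxel_to_mm(thr$grid, ijk)
      rows[[length(rows) + 1L]] <- data.frame(
        label = sprintf("%s_%d", sign_lab, l),
        x = mm[1], y = mm[2], z = mm[3],
        peak_t = thr$source$t[peak],
        voxels = length(vox)
      )
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(label = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), peak_t = numeric(0),
                      voxels = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$voxels), , drop = FALSE]
  rownames(out) <- NULL
  out
}
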