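#' Spatial correlation between two statistical maps
#'
#' Pearson correlation of the two t fields over the masked voxels.
#'
#' @param a,b `stat_map` objects on the same grid.
#' @param mask logical array; defaults to the shared brain mask.
#' @return scalar correlation.
#' @export
spatial_correlation <- function(a, b, mask = NULL) {
  stopifnot(inherits(a, "stat_map"), inherits(b, "stat_map"))
  check_same_grid(a$grid, b$grid, "stat maps")
  if (is.null(mask)) mask <- a$grid$brain_mask
  if (sum(mask) < 3) stop("mask must contain at least 3 voxels")
  va <- a$t[mask]; vb <- b$t[mask]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("spatial correlation undefined: a map is constant on the mask")
  }
  stats::cor(va, vb)
}

#' Transform a spatial correlation into a dissimilarity distance
#'
#' @param r correlation(s) in `[-1, 1]`.
#' @param method `"one_minus_r"` (default, d = 1 - r, so the conventional cut
#'   at 0.4 corresponds to r = 0.6), `"sqrt_two_one_minus_r"`
#'   (d = sqrt(2 (1 - r))) or `"half_one_minus_r"` (d = (1 - r) / 2).
#' @return dissimilarities, same length as `r`; d(1) = 0 for every method.
#' @export
dissimilarity <- function(r, method = c("one_minus_r", "sqrt_two_one_minus_r",
                                        "half_one_minus_r")) {
  method <- match.arg(method)
  if (any(abs(r) > 1 + 1e-12)) stop("correlations must lie in [-1, 1]")
  r <- pmin(pmax(r, -1), 1)
  switch(method,
         one_minus_r = 1 - r,
         sqrt_two_one_minus_r = sqrt(2 * (1 - r)),
         half_one_minus_r = (1 - r) / 2)
}

#' Pairwise map distance matrix
#'
#' Spatial correlations between every pair of network maps, and their
#' dissimilarity transform.
#'
#' @param maps named list of `stat_map` objects (conventionally nine, one per
#'   seed).
#' @param mask correlation mask; defaults to the shared brain mask.
#' @param method dissimilarity formula, see [dissimilarity()].
#' @return a `map_distance_matrix`: list with `labels`, `r` (correlations,
#'   unit diagonal) and `d` (dissimilarities, zero diagonal).
#' @export
map_distance_matrix <- function(maps, mask = NULL,
                                method = "one_minus_r") {
  labels <- names(maps)
  if (is.null(labels)) labels <- vapply(maps, `[[`, "", "seed_name")
  m <- length(maps)
  r <- diag(1, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      r[i, j] <- r[j, i] <- spatial_correlation(maps[[i]], maps[[j]], mask)
    }
  }
  d <- dissimilarity(r, method)
  diag(d) <- 0
  dimnames(r) <- dimnames(d) <- list(labels, labels)
  structure(list(labels = labels, r = r, d = d, method = method),
            class = "map_distance_matrix")
}

#' @export
print.map_distance_matrix <- function(x, ...) {
  cat(sprintf("map_distance_matrix (%d maps, %s):\n", length(x$labels),
              x$method))
  print(round(x$d, 3))
  invisible(x)
}

#' Hierarchical clustering of network maps
#'
#' Agglomerative clustering of the dissimilarity matrix, merging at each step
#' the pair of clusters with minimal inter-cluster distance under the linkage
#' rule, then cutting the tree at a distance threshold.
#'
#' @param dm a `map_distance_matrix`, or a symmetric numeric dissimilarity
#'   matrix with dimnames.
#' @param linkage `"average"` (default), `"single"` or `"complete"`.
#' @param cut_height tree cut distance; the conventional threshold is 0.4.
#' @return a `network_clustering`: list with the `hclust` tree, the linkage,
#'   cut height, the integer `partition` (named by map), and `n_clusters`.
#' @export
hierarchical_cluster <- function(dm, linkage = c("average", "single",
                                                 "complete"),
                                 cut_height = 0.4) {
  linkage <- match.arg(linkage)
  d <- if (inherits(dm, "map_distance_matrix")) dm$d else as.matrix(dm)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) || any(diag(d) != 0)) {
    stop("dissimilarity matrix must be symmetric with zero diagonal")
  }
  tree <- stats::hclust(stats::as.dist(d), method = linkage)
  partition <- stats::cutree(tree, h = cut_height)
  structure(
    list(tree = tree, linkage = linkage, cut_height = cut_height,
         partition = partition, n_clusters = max(partition)),
    class = "network_clustering"
  )
}

#' @export
print.network_clustering <- function(x, ...) {
  cat(sprintf("network_clustering (%s linkage, cut %.3g): %d clusters\n",
              x$linkage, x$cut_height, x$n_clusters))
  for (k in seq_len(x$n_clusters)) {
    cat(sprintf("  cluster %d: %s\n", k,
                paste(names(x$partition)[x$partition == k], collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.network_clustering <- function(x, ...) {
  plot(x$tree, ylab = "dissimilarity", ...)
  stats::rect.hclust(x$tree, h = x$cut_height)
  invisible(x)
}

# Shared counting core of the conjunction rules: given lists of pos/neg
# significance masks and t fields, build the k-of-n sign-consistent masks
# and the mean-t field restricted to them.
conjunction_core <- function(pos_masks, neg_masks, t_fields, grid, k, rule) {
  n <- length(pos_masks)
  pos_count <- Reduce(`+`, lapply(pos_masks, function(m) m * 1L))
  neg_count <- Reduce(`+`, lapply(neg_masks, function(m) m * 1L))
  pos_mask <- array(pos_count >= k, dim = grid$shape)
  neg_mask <- array(neg_count >= k, dim = grid$shape)
  mean_t <- Reduce(`+`, t_fields) / n
  mean_t[!(pos_mask | neg_mask)] <- NA_real_
  structure(
    list(grid = grid, pos_mask = pos_mask, neg_mask = neg_mask,
         mean_t = mean_t, k = k, n = n, rule = rule),
    class = "conjunction_map"
  )
}

#' @export
print.conjunction_map <- function(x, ...) {
  cat(sprintf("conjunction_map (%s, >= %d of %d): %d positive, %d negative voxels\n",
              x$rule, x$k, x$n, sum(x$pos_mask), sum(x$neg_mask)))
  invisible(x)
}

#' Intra-set conjunction of thresholded maps
#'
#' A voxel enters the positive mask when it is significantly positive in at
#' least `k` of the maps, and the negative mask when significantly negative
#' in at least `k`; the two signs never mix. The mean-t field averages the
#' unthresholded t maps and is reported only inside the masks.
#'
#' @param thr_maps list of `thresholded_map` (conventionally the 3 maps of
#'   one seed set).
#' @param k minimum number of agreeing maps, default 2.
#' @return a `conjunction_map`.
#' @export
conjunction_intra_set <- function(thr_maps, k = 2L) {
  stopifnot(length(thr_maps) >= 1,
            all(vapply(thr_maps, inherits, TRUE, "thresholded_map")))
  grid <- thr_maps[[1]]$grid
  for (m in thr_maps[-1]) check_same_grid(grid, m$grid, "thresholded maps")
  conjunction_core(
    lapply(thr_maps, `[[`, "pos_mask"),
    lapply(thr_maps, `[[`, "neg_mask"),
    lapply(thr_maps, function(m) m$source$t),
    grid, k, rule = "intra-set"
  )
}

#' Inter-set conjunction with one sign-flipped set
#'
#' The maps of `flip_set` (conventionally the sensory set) are sign-inverted
#' — their t fields negated and their positive/negative masks swapped — and
#' the k-of-n counting rule of [conjunction_intra_set()] is then applied to
#' all maps together. The resulting positive mask is the high-level
#' (DMN + TPN) system, the negative mask the low-level sensory system.
#'
#' @param thr_map_sets named list of lists of `thresholded_map`, one entry
#'   per seed set (e.g. DMN, TPN, SN with 3 maps each).
#' @param flip_set name of the set to sign-flip, default `"SN"`.
#' @param k minimum number of sign-consistent maps, default 8.
#' @return a `conjunction_map`.
#' @export
conjunction_inter_set <- function(thr_map_sets, flip_set = "SN", k = 8L) {
  stopifnot(flip_set %in% names(thr_map_sets))
  pos <- list(); neg <- list(); tf <- list()
  grid <- thr_map_sets[[1]][[1]]$grid
  for (set_name in names(thr_map_sets)) {
    for (m in thr_map_sets[[set_name]]) {
      stopifnot(inherits(m, "thresholded_map"))
      check_same_grid(grid, m$grid, "thresholded maps")
      if (set_name == flip_set) {
        pos[[length(pos) + 1L]] <- m$neg_mask
        neg[[length(neg) + 1L]] <- m$pos_mask
        tf[[length(tf) + 1L]] <- -m$source$t
      } else {
        pos[[length(pos) + 1L]] <- m$pos_mask
        neg[[length(neg) + 1L]] <- m$neg_mask
        tf[[length(tf) + 1L]] <- m$source$t
      }
    }
  }
  conjunction_core(pos, neg, tf, grid, k,
                   rule = sprintf("inter-set (flip %s)", flip_set))
}

#' Within-subject network dichotomy of seed correlation maps
#'
#' Per subject, the DMN seed maps are multiplied by -1 and averaged together
#' with the TPN seed maps; the combined maps are taken to the group level by
#' a covariate-adjusted one-sample t test and FWE-thresholded, yielding the
#' task-positive (positive mask) versus default-mode (negative mask)
#' dichotomy.
#'
#' @param dmn_maps,tpn_maps lists over subjects of 3D Fisher-z arrays; each
#'   element may itself be a list of the set's per-seed maps, or a single
#'   pre-averaged array.
#' @param grid the `volume_grid`.
#' @param covariates subjects x c matrix for the group model, or NULL.
#' @param alpha FWE level for the masks, default 0.05.
#' @return list with the combined group `stat_map`, the `thresholded_map`,
#'   and the per-subject combined maps matrix.
#' @export
ts_icn_dichotomy <- function(dmn_maps, tpn_maps, grid, covariates = NULL,
                             alpha = 0.05) {
  stopifnot(length(dmn_maps) == length(tpn_maps))
  as_list <- function(x) if (is.list(x)) x else list(x)
  combined <- vapply(seq_along(dmn_maps), function(s) {
    dm <- as_list(dmn_maps[[s]])
    tp <- as_list(tpn_maps[[s]])
    fields <- c(lapply(dm, function(m) -m), tp)
    as.vector(Reduce(`+`, fields) / length(fields))
  }, numeric(n_voxels(grid)))
  combined <- t(combined) # subjects x voxels
  stat <- group_onesample_t(combined, grid, covariates,
                            estimator = "TS-ICN", seed_name = "dichotomy")
  thr <- fwe_threshold(stat, alpha)
  list(stat = stat, thresholded = thr, subject_maps = combined)
}

#' Two-system dichotomy statistics
#'
#' Per subject, the mean measure (conventionally standardized ALFF) inside
#' the high-level and low-level system masks; the Pearson correlation between
#' the two subject vectors with its two-sided p value, and the Welch
#' two-sample t comparing their levels with its two-sided p value.
#'
#' @param cohort a `cohort_matrix` (subjects x voxels).
#' @param high_mask,low_mask disjoint non-empty logical arrays.
#' @return a `dichotomy_result`: subject vectors, `r`, `r_pvalue`,
#'   `t_twosample`, `t_pvalue`, and per-system mean and SD.
#' @export
dichotomy_statistics <- function(cohort, high_mask, low_mask) {
  stopifnot(inherits(cohort, "cohort_matrix"))
  if (!any(high_mask) || !any(low_mask)) stop("system masks must be non-empty")
  if (any(high_mask & low_mask)) stop("system masks must be disjoint")
  high <- rowMeans(cohort$data[, as.vector(high_mask), drop = FALSE])
  low <- rowMeans(cohort$data[, as.vector(low_mask), drop = FALSE])
  ct <- stats::cor.test(high, low, method = "pearson")
  tt <- stats::t.test(high, low) # Welch
  structure(
    list(high = high, low = low,
         r = unname(ct$estimate), r_pvalue = ct$p.value,
         t_twosample = unname(tt$statistic), t_pvalue = tt$p.value,
         high_mean = mean(high), high_sd = stats::sd(high),
         low_mean = mean(low), low_sd = stats::sd(low),
         subject_ids = cohort$subject_ids),
    class = "dichotomy_result"
  )
}

#' @export
print.dichotomy_result <- function(x, ...) {
  cat(sprintf(
    "dichotomy_result: r = %.3f (P = %.3g), t = %.3f (P = %.3g)\n  high system %.3f +/- %.3f, low system %.3f +/- %.3f (n = %d)\n",
    x$r, x$r_pvalue, x$t_twosample, x$t_pvalue,
    x$high_mean, x$high_sd, x$low_mean, x$low_sd, length(x$high)))
  invisible(x)
}
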