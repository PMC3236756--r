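#' Volume grid: 3D raster geometry shared by all maps
#'
#' A `volume_grid` couples a raster shape with the affine mapping 0-based voxel
#' indices to world (MNI) millimetre coordinates, plus a brain mask. Every
#' scalar map, BOLD series and statistical map in a study lives on one grid;
#' operations check grid agreement before combining maps.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric matrix mapping homogeneous 0-based voxel indices
#'   to mm (RAS convention). Must be invertible.
#' @param brain_mask logical array of dim `shape`, or `NULL` for all-true.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, affine, brain_mask = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L))) {
    stop("affine must be a 4x4 matrix")
  }
  if (abs(det(affine[1:3, 1:3])) < .Machine$double.eps * 100) {
    stop("affine is not invertible")
  }
  if (is.null(brain_mask)) {
    brain_mask <- array(TRUE, dim = shape)
  }
  brain_mask <- array(as.logical(brain_mask), dim = shape)
  if (!any(brain_mask)) stop("brain_mask has no TRUE voxel")
  structure(
    list(shape = shape, affine = affine, brain_mask = brain_mask),
    class = "volume_grid"
  )
}

#' Construct an axis-aligned grid from voxel size and origin
#'
#' Convenience constructor for isotropic or anisotropic axis-aligned grids:
#' voxel (i,j,k) maps to `origin_mm + c(i,j,k) * voxel_mm`.
#'
#' @param shape integer triple.
#' @param voxel_mm voxel edge lengths in mm (length 1 or 3).
#' @param origin_mm mm coordinate of voxel (0,0,0); default centres the grid
#'   on (0,0,0).
#' @param brain_mask optional logical array.
#' @export
grid_from_spacing <- function(shape, voxel_mm = 3, origin_mm = NULL,
                              brain_mask = NULL) {
  shape <- as.integer(shape)
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (is.null(origin_mm)) origin_mm <- -(shape - 1L) / 2 * voxel_mm
  affine <- diag(c(voxel_mm, 1))
  affine[1:3, 4] <- origin_mm
  volume_grid(shape, affine, brain_mask)
}

#' @export
print.volume_grid <- function(x, ...) {
  vs <- voxel_size(x)
  cat(sprintf(
    "volume_grid: %d x %d x %d voxels, %.3g x %.3g x %.3g mm, %d in brain mask\n",
    x$shape[1], x$shape[2], x$shape[3], vs[1], vs[2], vs[3],
    sum(x$brain_mask)
  ))
  invisible(x)
}

#' Voxel edge lengths in mm
#' @param grid a `volume_grid`.
#' @return numeric length-3 vector.
#' @export
voxel_size <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

n_voxels <- function(grid) prod(grid$shape)

#' World mm coordinates of all voxel centres
#'
#' @param grid a `volume_grid`.
#' @return `prod(shape)` x 3 matrix in array (column-major) voxel order.
#' @export
voxel_centers_mm <- function(grid) {
  idx <- as.matrix(expand.grid(
    i = seq_len(grid$shape[1]) - 1L,
    j = seq_len(grid$shape[2]) - 1L,
    k = seq_len(grid$shape[3]) - 1L
  ))
  xyz <- cbind(idx, 1) %*% t(grid$affine)
  xyz[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel indices to mm
#' @param grid a `volume_grid`.
#' @param ijk n x 3 matrix of 0-based voxel indices.
#' @export
voxel_to_mm <- function(grid, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  out <- cbind(ijk, 1) %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' Test whether two grids share shape and affine
#' @param a,b `volume_grid` objects.
#' @param tol affine agreement tolerance in mm.
#' @export
same_grid <- function(a, b, tol = 1e-4) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

check_same_grid <- function(a, b, what = "maps") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch between %s (shape/affine disagree)", what))
  }
  invisible(TRUE)
}

#' Seed region of interest: a sphere in world coordinates
#'
#' @param name region label (e.g. "PCC").
#' @param center_mm MNI mm centre, length 3.
#' @param radius_mm sphere radius in mm; the shipped networks use 6 mm.
#' @param set optional network-set label ("DMN", "TPN" or "SN").
#' @return an object of class `seed_roi`.
#' @export
seed_roi <- function(name, center_mm, radius_mm = 6, set = NA_character_) {
  stopifnot(is.character(name), length(center_mm) == 3)
  radius_mm <- as.numeric(radius_mm)
  if (!is.finite(radius_mm) || radius_mm <= 0) {
    stop("radius_mm must be a positive number")
  }
  structure(
    list(name = name, center_mm = as.numeric(center_mm),
         radius_mm = radius_mm, set = set),
    class = "seed_roi"
  )
}

#' @export
print.seed_roi <- function(x, ...) {
  cat(sprintf("seed_roi %s [%s]: centre (%g, %g, %g) mm, radius %g mm\n",
              x$name, x$set, x$center_mm[1], x$center_mm[2], x$center_mm[3],
              x$radius_mm))
  invisible(x)
}

#' The nine canonical seed regions
#'
#' Three seed sets of three 6-mm spheres each: the default-mode network
#' (PCC, DMPFC, left AG), the task-positive network (right DLPFC, left IPL,
#' left FEF) and the sensory networks (left S1, left V1, left A1), at their
#' standard MNI coordinates.
#'
#' @param scale multiply all centre coordinates by this factor (the synthetic
#'   desk-scale grid uses 0.35 to fit its small field of view).
#' @param radius_mm sphere radius, default 6 mm.
#' @return a list of nine `seed_roi` objects, attribute `sets` giving the
#'   set label of each.
#' @export
default_seed_rois <- function(scale = 1, radius_mm = 6) {
  tab <- list(
    list("PCC",   c(0, -56, 30),   "DMN"),
    list("DMPFC", c(0, 54, 30),    "DMN"),
    list("AG",    c(-45, -66, 30), "DMN"),
    list("DLPFC", c(42, 45, 26),   "TPN"),
    list("IPL",   c(-20, -60, 54), "TPN"),
    list("FEF",   c(-26, 2, 52),   "TPN"),
    list("SC",    c(-50, -24, 46), "SN"),
    list("VC",    c(-20, -84, -4), "SN"),
    list("AC",    c(-60, -18, 2),  "SN")
  )
  rois <- lapply(tab, function(r) {
    seed_roi(r[[1]], r[[2]] * scale, radius_mm, set = r[[3]])
  })
  names(rois) <- vapply(rois, `[[`, "", "name")
  attr(rois, "sets") <- vapply(rois, `[[`, "", "set")
  rois
}

#' Resolve a spherical ROI to a voxel mask
#'
#' A voxel belongs to the sphere when its centre's Euclidean mm distance to
#' the ROI centre is at most the radius; the result is intersected with the
#' grid's brain mask.
#'
#' @param roi a `seed_roi`.
#' @param grid a `volume_grid`.
#' @return logical array of dim `grid$shape`.
#' @export
sphere_roi_mask <- function(roi, grid) {
  xyz <- voxel_centers_mm(grid)
  d2 <- (xyz[, 1] - roi$center_mm[1])^2 +
    (xyz[, 2] - roi$center_mm[2])^2 +
    (xyz[, 3] - roi$center_mm[3])^2
  mask <- array(d2 <= roi$radius_mm^2, dim = grid$shape) & grid$brain_mask
  if (!any(mask)) {
    stop(sprintf("ROI '%s' has no voxel inside the brain mask", roi$name))
  }
  mask
}

#' Unweighted mean of a map or BOLD series over a voxel mask
#'
#' @param x a 3D numeric array (scalar map) or a `bold4d`.
#' @param mask logical array on the same grid.
#' @return a scalar for a map; a length-T time series for a `bold4d`.
#' @export
roi_mean <- function(x, mask) {
  if (!any(mask)) stop("empty mask in roi_mean")
  if (inherits(x, "bold4d")) {
    stopifnot(identical(dim(mask), x$grid$shape))
    return(rowMeans(x$data[, as.vector(mask), drop = FALSE]))
  }
  stopifnot(identical(dim(x), dim(mask)))
  mean(x[mask])
}

#' Read a seed-ROI specification file
#'
#' YAML or JSON list of records with fields `name`, `set`, `x`, `y`, `z` and
#' optional `radius` (default 6 mm).
#'
#' @param path file path.
#' @return list of `seed_roi` objects with a `sets` attribute.
#' @export
read_roi_spec <- function(path) {
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext == "json") {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  rois <- lapply(recs, function(r) {
    seed_roi(r$name, c(r$x, r$y, r$z),
             radius_mm = if (is.null(r$radius)) 6 else r$radius,
             set = if (is.null(r$set)) NA_character_ else r$set)
  })
  names(rois) <- vapply(rois, `[[`, "", "name")
  if (anyDuplicated(names(rois))) stop("duplicate ROI names in spec")
  attr(rois, "sets") <- vapply(rois, `[[`, "", "set")
  rois
}

#' Write a seed-ROI specification file (YAML)
#' @param rois list of `seed_roi`.
#' @param path output path.
#' @export
write_roi_spec <- function(rois, path) {
  recs <- lapply(rois, function(r) {
    list(name = r$name, set = r$set, x = r$center_mm[1], y = r$center_mm[2],
         z = r$center_mm[3], radius = r$radius_mm)
  })
  names(recs) <- NULL
  yaml::write_yaml(recs, path)
  invisible(path)
}

#' Group a list of ROIs by their set label
#' @param rois list of `seed_roi` with set labels.
#' @return named list of lists, one per set, in first-appearance order.
#' @export
split_roi_sets <- function(rois) {
  sets <- vapply(rois, `[[`, "", "set")
  if (anyNA(sets)) stop("all ROIs need a set label to be grouped")
  lapply(split(seq_along(rois), factor(sets, levels = unique(sets))),
         function(i) rois[i])
}
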