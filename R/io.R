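#' Write a 3D scalar map as NIfTI
#'
#' @param values 3D numeric (or logical) array on `grid`.
#' @param grid a `volume_grid` supplying the affine.
#' @param path output path (.nii or .nii.gz).
#' @export
write_volume <- function(values, grid, path) {
  stopifnot(identical(dim(values), grid$shape))
  img <- RNifti::asNifti(array(as.numeric(values), dim = grid$shape))
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 3D NIfTI volume
#'
#' @param path file path.
#' @param brain_mask optional logical array for the returned grid.
#' @return list with `values` (3D array) and `grid` (a `volume_grid`).
#' @export
read_volume <- function(path, brain_mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop(sprintf("%s is not a 3D volume", path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- volume_grid(d, aff, brain_mask)
  list(values = array(as.numeric(img), dim = d), grid = grid)
}

#' Write a 4D BOLD series as NIfTI plus a JSON sidecar
#'
#' The sidecar (same path with extension `.json`) records the repetition
#' time; [read_bold()] prefers it over the NIfTI header.
#'
#' @param bold a `bold4d`.
#' @param path output path.
#' @export
write_bold <- function(bold, path) {
  nt <- nrow(bold$data)
  arr <- array(t(bold$data), dim = c(bold$grid$shape, nt))
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(bold$grid$affine, code = 2L))
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(tr_seconds = bold$tr_seconds),
                       sidecar_path(path), auto_unbox = TRUE)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a 4D BOLD NIfTI
#'
#' @param path file path.
#' @param tr_seconds repetition time override; if `NULL`, taken from the
#'   JSON sidecar, else from the header's 4th pixdim.
#' @param brain_mask optional logical array for the grid.
#' @return a `bold4d`.
#' @export
read_bold <- function(path, tr_seconds = NULL, brain_mask = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop(sprintf("%s is not a 4D volume", path))
  if (is.null(tr_seconds)) {
    sc <- sidecar_path(path)
    if (file.exists(sc)) {
      tr_seconds <- jsonlite::fromJSON(sc)$tr_seconds
    } else {
      pd <- RNifti::pixdim(img)
      if (length(pd) >= 4 && pd[4] > 0) tr_seconds <- pd[4]
    }
  }
  if (is.null(tr_seconds)) {
    stop(sprintf("no repetition time for %s: provide tr_seconds or a sidecar", path))
  }
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  grid <- volume_grid(d[1:3], aff, brain_mask)
  bold4d(t(matrix(as.numeric(img), nrow = prod(d[1:3]), ncol = d[4])),
         grid, tr_seconds)
}

#' Read a phenotype table (TSV or CSV)
#'
#' Requires columns `subject_id`, `center`, `sex`, `age`; `tcv` and `gmv`
#' are optional. Subject ids must be unique and used covariates complete.
#'
#' @param path file path; the separator follows the extension (.tsv/.csv).
#' @return data.frame with `center` and `sex` as factors.
#' @export
read_phenotype <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("subject_id", "center", "sex", "age")
  missing_cols <- setdiff(need, colnames(tab))
  if (length(missing_cols)) {
    stop("phenotype table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(tab$subject_id)) stop("duplicate subject_id in phenotype")
  if (anyNA(tab[need])) stop("missing values in required phenotype columns")
  tab$center <- factor(tab$center)
  tab$sex <- factor(tab$sex)
  tab
}

#' Write an ALFF map as NIfTI with a JSON sidecar
#'
#' The sidecar records the band, repetition time and standardization flag.
#'
#' @param alff an `alff_map`.
#' @param path output path (.nii or .nii.gz).
#' @export
write_alff_map <- function(alff, path) {
  stopifnot(inherits(alff, "alff_map"))
  write_volume(alff$values, alff$grid, path)
  jsonlite::write_json(
    list(band_hz = alff$band_hz, tr_seconds = alff$tr_seconds,
         standardized = alff$standardized),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a thresholded stat map bundle
#'
#' Writes the t map, the positive and negative significance masks, and a
#' JSON provenance sidecar (estimator, seed, df, alpha, critical t).
#'
#' @param thr a `thresholded_map`.
#' @param prefix output path prefix (files `<prefix>_t.nii.gz`,
#'   `<prefix>_pos.nii.gz`, `<prefix>_neg.nii.gz`, `<prefix>.json`).
#' @export
write_thresholded_map <- function(thr, prefix) {
  g <- thr$grid
  write_volume(thr$source$t, g, paste0(prefix, "_t.nii.gz"))
  write_volume(thr$pos_mask, g, paste0(prefix, "_pos.nii.gz"))
  write_volume(thr$neg_mask, g, paste0(prefix, "_neg.nii.gz"))
  jsonlite::write_json(
    list(estimator = thr$source$estimator, seed = thr$source$seed_name,
         df = thr$source$df, alpha_fwe = thr$alpha_fwe, t_crit = thr$t_crit,
         n_comparisons = thr$n_comparisons,
         n_pos = sum(thr$pos_mask), n_neg = sum(thr$neg_mask)),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Write a cluster table as TSV
#' @param tab data.frame from [cluster_table()].
#' @param path output path.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
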